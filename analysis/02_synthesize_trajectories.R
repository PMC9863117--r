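#!/usr/bin/env Rscript
# Step 2 — synthetic conformational trajectories with exact ground truth.
#
# In place of molecular-dynamics sampling, designated segments of each
# peptide switch between a helical dihedral basin and extended coil basins
# under a seeded two-state Markov chain. This writes a small demonstration
# batch as multi-model PDB (the same format an MD post-processing run would
# consume) together with the designed per-residue occupancies, and verifies
# that the assigner sees what the generator planted.

library(peptraj)

out_dir <- "results/trajectories"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cases <- data.frame(id = c("demo_weak", "demo_half", "demo_strong"),
                    occupancy = c(0.2, 0.5, 0.9))
seqs <- generate_sequences(builtin_set("GADVE"), n = nrow(cases), length = 20,
                           seed = 7L)

for (k in seq_len(nrow(cases))) {
  spec <- synthetic_spec(seqs$sequence[k],
                         data.frame(start = 5, end = 15,
                                    occupancy = cases$occupancy[k]),
                         n_frames = 400, seed = 100L + k)
  syn <- synthesize_trajectory(spec)
  pdb <- file.path(out_dir, paste0(cases$id[k], ".pdb"))
  write_trajectory(syn$trajectory, pdb)
  write.csv(syn$truth, file.path(out_dir, paste0(cases$id[k], "_truth.csv")),
            row.names = FALSE)
  # round-trip through the PDB reader, then measure
  occ <- helix_occupancy(assign_trajectory(read_trajectory(pdb)))
  interior <- syn$truth$role == "interior"
  cat(sprintf(
    "%s: designed occupancy %.2f, measured interior occupancy %.3f (realized state freq %.3f)\n",
    cases$id[k], cases$occupancy[k], mean(occ[interior]),
    mean(syn$truth$realized_occupancy[interior])))
}
cat("Measured occupancies track the realized Markov-state frequencies;",
    "the 0.5 case sits at the helix-residue classification boundary.\n")
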