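#!/usr/bin/env Rscript
# Step 1 — amino-acid sets and random peptide libraries.
#
# Defines the five restricted alphabets (the primitive GADV set, the
# alanine-doubled GADVA control, the five-letter GADVE / GADVL extensions and
# the codon-ratio GA(D/E)V set) and draws 100 random 20-mers per set with
# composition-weighted, seeded sampling. Writes one FASTA per set plus a
# pooled composition table to check the realized residue frequencies.

library(peptraj)

seed <- 20230116L
out_dir <- "results/sequences"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (name in names(builtin_sets())) {
  set <- builtin_set(name)
  seqs <- generate_sequences(set, n = 100, length = 20, seed = seed)
  safe <- gsub("[^A-Za-z0-9]", "", name)
  write_fasta(seqs, file.path(out_dir, paste0(safe, ".fasta")))
  pool <- strsplit(paste(seqs$sequence, collapse = ""), "")[[1]]
  p <- set_probabilities(set)
  realized <- table(factor(pool, levels = names(p))) / length(pool)
  rows[[name]] <- data.frame(set = name, residue = names(p),
                             target = as.numeric(p),
                             realized = as.numeric(realized))
  cat(sprintf("%-9s: 100 x 20-mers; max |realized - target| = %.4f\n",
              name, max(abs(as.numeric(realized) - as.numeric(p)))))
}
comp <- do.call(rbind, rows)
rownames(comp) <- NULL
write.csv(comp, file.path(out_dir, "composition.csv"), row.names = FALSE)
cat("Realized compositions track the target ratios at n*L = 2000 draws per set",
    "(sampling error ~ 1/sqrt(2000) ~ 0.02); see", file.path(out_dir, "composition.csv"), "\n")
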