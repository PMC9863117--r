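# peptraj

Structure-formation analysis for short peptides built from restricted
amino-acid alphabets.

## The problem

A recurring model of the earliest proteins is the random 20-mer drawn from a
restricted alphabet: the four-letter **GADV** set (Gly, Ala, Asp, Val — the
GNC codon block) and five-letter extensions that add glutamate (**GADVE**),
leucine (**GADVL**), double alanine (**GADVA**), or weight the alphabet by
codon multiplicity (**GA(D/E)V**, G:A:D:V:E = 2:2:1:2:1). Given
conformational ensembles of such peptides — typically the tail window of a
molecular-dynamics trajectory — the scientific questions are statistical:
how many residues hold secondary structure, how rigid are the chains, how
many hydrogen bonds form, and how does structure formation trade off against
the polar fraction of the accessible surface (a hydrophilicity index)?

`peptraj` implements that measurement pipeline for trajectory ensembles,
plus a seeded synthetic-trajectory generator with exact ground truth so the
whole pipeline is testable without running MD. It is aimed at people
analysing (or teaching about) reduced-alphabet peptide ensembles: MD
post-processing without external assigner/surface binaries, with every stage
unit-tested against independent oracles.

## What it computes

For a trajectory window (multi-model PDB, or built in memory):

* **Kabsch–Sander secondary structure** per frame: backbone H-bonds from the
  electrostatic proxy energy
  `E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol`,
  then n-turns, minimal helices (H/G/I), bridges/ladders (E/B), turns and
  bends, priority H > E > B > G > I > T > S.
* **Helix residues**: residues helical (H, G or I) in ≥ 50% of frames;
  helix content = mean helix-mask over frames × residues.
* **Rigid residues**: Cα RMSF < 4.0 Å about the iterated average structure
  after unweighted all-Cα superposition (Kabsch, SVD).
* **Hydrogen bonds**: geometric criterion, X–H…X′ angle ≥ 120° and
  H…X′ distance ≤ 3.5 Å, all N/O donors/acceptors, intra-residue pairs
  excluded; mean count per frame.
* **Surfaces**: Shrake–Rupley SASA (Bondi radii, 1.4 Å probe, 960-point
  deterministic spiral), polar surface area over N/O/polar-H, and the
  PSA/SASA hydrophilicity ratio of trajectory means.
* **Per-set statistics**: histograms of helix/rigid counts (zero-count
  peptides tallied separately), per-set means, set rankings with pairwise
  differences, and Pearson's r between helix content and PSA/SASA.

The synthetic generator plants segments that switch between helical and coil
dihedral basins under a seeded two-state Markov chain with known occupancy,
so occupancy recovery, RMSF analytics and H-bond counts can be checked
against ground truth. The methods vignette
(`vignettes/peptraj-methods.Rmd`) gives the full model description and
design rationale.

## Worked example

```r
library(peptraj)

# 1. a random GADVE 20-mer
seqs <- generate_sequences(builtin_set("GADVE"), n = 1, length = 20, seed = 42)
seqs$sequence
#> [1] "AGVGADDVGAGGVGAVAEVD"

# 2. a synthetic 2000-frame trajectory: residues 5-15 helical 80% of the time
spec <- synthetic_spec(seqs$sequence, data.frame(start = 5, end = 15,
                                                 occupancy = 0.8),
                       n_frames = 2000, seed = 1)
traj <- synthesize_trajectory(spec)$trajectory

# 3. the full measurement stack
pm <- peptide_metrics(traj, surface = TRUE, surface_stride = 50)
round(as.data.frame(pm$peptide[, 3:10]), 3)
#>   n_helix_residues n_rigid_residues mean_hbonds helix_content mean_rmsf_ca
#> 1               11               13      11.591         0.456        3.693
#>       sasa    psa psa_ratio
#> 1 1990.475 927.25     0.466
```

Eleven residues (5–15) clear the 50% occupancy threshold; the helix content
0.456 matches the planted 11 × 0.8 / 20 = 0.44 within sampling error; 13
residues are rigid (the helical block and its flanks — the free coil tails
fluctuate above the 4 Å cutoff); and about 47% of the accessible surface is
polar. Aggregating many such peptides per alphabet and comparing
sets is what the scripts under `analysis/` do (`01_generate_sets.R` …
`04_summarize_sets.R`, writing tables under `results/`).

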