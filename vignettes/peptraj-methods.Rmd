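---
title: "Measuring structure formation in restricted-alphabet peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring structure formation in restricted-alphabet peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptraj)
```

## The scientific question

Candidate primitive proteins are often modelled as short random peptides
drawn from restricted amino-acid alphabets: the four-letter GADV set
(glycine, alanine, aspartate, valine, the residues of the GNC codon block)
and five-letter extensions that add glutamate (GADVE), leucine (GADVL), or
re-weight the alphabet by codon multiplicity (GA(D/E)V, with
G:A:D:V:E = 2:2:1:2:1). The question asked of such ensembles is statistical:
across many random 20-mers, how often and how strongly do peptides of each
alphabet form ordered structure, and at what cost in water solubility?

`peptraj` implements the measurement side of that programme as a tested
pipeline. Its input is a conformational ensemble per peptide — frames of a
trajectory in multi-model PDB — and its output is the per-peptide and
per-set statistics: helix residues, rigid residues, hydrogen-bond counts,
solvent-accessible and polar surface areas, and their per-set aggregation.
Molecular dynamics itself is deliberately out of scope; a seeded synthetic
trajectory generator with exact ground truth stands in for it, so that every
stage of the measurement machinery is testable at desk scale.

## The measurement model

**Secondary structure.** Per frame, residues are labelled by a full
reimplementation of the Kabsch–Sander hydrogen-bond pattern analysis. A
backbone H-bond between the amide N–H of residue *d* and the carbonyl C=O of
residue *a* (|d − a| ≥ 2) is declared when the electrostatic proxy energy

E = 0.084 · 332 · (1/r(ON) + 1/r(CH) − 1/r(OH) − 1/r(CN))  kcal/mol

falls below −0.5 kcal/mol (distances in Å; E clamped at −9.9; at most the
two lowest-energy acceptors per donor count). n-turns at offsets 3/4/5 give
minimal helices (G/H/I) from two consecutive turns; bridges give ladders and
sheets (B/E) with single-bulge linking; turns (T) and bends (S, Cα curvature
above 70°) complete the alphabet, with priority H > E > B > G > I > T > S.
The amide hydrogen is reconstructed 1.01 Å from N along the preceding
C=O direction — the convention of the original assigner — whether or not the
input carries hydrogens, so the stage is total on heavy-atom trajectories.
π-helices are assigned at lower priority than α (H wins overlaps), matching
the distributed assigner's behaviour. In tests the implementation is held to
≥ 95% per-residue label agreement (≥ 98% on the helix mask) against an
independent reference implementation on mixed helix/coil fixtures; the
remaining disagreements sit at helix termini where assigner variants
genuinely differ, which is why agreement, not bit-exactness, is the
acceptance surface.

**Helix residues and occupancy.** α-, 3₁₀- and π-helix labels all count as
"helix". A residue is a *helix residue* when it is helical in at least 50%
of analysis-window frames (the boundary is inclusive and configurable); the
per-peptide count and the helix content (mean of the helix mask over frames
× residues) are the headline secondary-structure statistics.

**Rigidity.** Frames are superposed (all Cα, unweighted) on an iterated
average structure — superpose on the running mean, recompute, to
convergence (mean shift < 1e-6 Å or 10 iterations) — and
RMSF_i = sqrt(mean_f |r_i(f) − r̄_i|²). Residues with RMSF < 4.0 Å (strict)
are *rigid residues*. The superposition protocol (all-Cα, unweighted, to the
iterated average) is the common trajectory-toolkit default; mass-weighting
is not applied.

**Hydrogen bonds.** The geometric criterion: donor X–H and acceptor X′
qualify when the X–H…X′ angle is ≥ 120° and the H…X′ distance ≤ 3.5 Å.
All N/O donors and acceptors participate (backbone, side chains, termini),
intra-residue pairs are excluded, and no minimum sequence separation is
imposed; a `backbone_only` switch covers the stricter reading. The reported
statistic is the mean qualifying-triple count per frame.

**Surfaces.** Solvent-accessible surface area uses Shrake–Rupley point
sampling: each atom's expanded sphere (Bondi radius + 1.4 Å probe) carries a
deterministic golden-section spiral of 960 points; a point is accessible if
outside every other expanded sphere. A dot-surface program served this role
in the original protocol; since the analysis uses surface areas only as a
relative hydrophilicity index, the algorithm substitution preserves the
semantics, and the implementation is checked against closed forms (isolated
sphere, two-sphere caps) and an established surface library. Polar surface
area sums N, O and N/O-bonded hydrogens (charged carboxylate oxygens are
polar); the hydrophilicity index is PSA/SASA as a ratio of trajectory means
(not the mean of per-frame ratios — the difference is second order, and the
ratio-of-means form keeps the [0, 1] bound exact under averaging). Polar
hydrogens are included by default; a heavy-atom-only mode is provided
because protocols differ on this point.

**Set statistics.** Histograms count peptides with ≥ 1 qualifying residue,
with zero-count peptides tallied separately (the usual presentation for such
campaigns); means are unweighted arithmetic means over all peptides
including zero-count ones; the helix-content vs PSA/SASA association is
Pearson's r (Spearman optional), reported as undefined — never silently 0 —
when either variable is constant.

## Peptide chemistry and construction

Conformations are built from internal coordinates by sequential natural
extension (NeRF), using standard backbone bond lengths/angles and ideal
side-chain geometry for G, A, D, V, E, L (templates shipped as plain-text
package data). The protonation convention matches the simulated chemistry:
D/E side chains and the C-terminal carboxylate are deprotonated (two
oxygens, 1.25 Å, no hydrogen) and the N-terminus is an ammonium group with
three hydrogens. Only heavy atoms and polar hydrogens are represented —
apolar hydrogens affect none of the four measurement stages. Default
side-chain rotamers are common rotamer-library states (χ1 = 180° throughout;
χ2 = 60° for L, −30° for D, 180° for E; χ3 = −30° for E), chosen once so
that default fixtures are clash-free in both helical and extended backbones.

## The synthetic-trajectory generator

Each designated segment of a peptide switches between a helical state
((φ, ψ) = (−57°, −47°) plus Gaussian jitter) and a coil state (β/PPII-region
basins with the same jitter) under a two-state Markov chain whose stationary
frequency is the designed *occupancy* and whose persistence (default 0.9)
emulates the frame-to-frame autocorrelation of MD output at sub-picosecond
spacing. Helix formation is modelled at segment level — cooperative blocks,
not per-residue coin flips — because the assigner's pattern rules require at
least two consecutive n-turns; independent per-residue states would almost
never produce an assignable helix. Dihedral jitter defaults to 8°, a
realistic backbone fluctuation within a folded basin; at this level the
assigner detects the helical state in ≈ 97–100% of helical frames for
interior residues, and pure-coil ensembles are called helical in < 1% of
residue-frames. Error bars on occupancy estimates use the effective sample
size n(1 − ρ)/(1 + ρ) of the persistent chain, not the raw frame count
(`occupancy_se()`).

Ground truth distinguishes *interior* segment residues (start+1 … end−1),
whose measured occupancy tracks the realized state frequency essentially
without attenuation, from *edge* residues, where helix termini make the
detected span assigner-dependent; accuracy claims are made on interior and
coil residues only.

What the generator does **not** emulate: force-field energetics, solvent,
side-chain packing, sheet formation, or any claim that its occupancies match
a particular force field's propensities. Passing tests demonstrate that the
measurement machinery is correct and well-calibrated, not that the synthetic
ensembles are physical.

## The synthetic set experiment

`synthetic_set_experiment()` emulates the design of a per-set simulation
campaign: random sequences per alphabet, one seeded trajectory per peptide,
the full measurement stack, per-set aggregation. Since synthetic peptides
have no physics, helix propensity enters through a monotone per-residue map
(default: E = 1.00, L = 0.95, A = 0.26, V = 0.25, D = 0.24, G = 0.23) and a
documented monotone rule: each of the two fixed 10-residue segment windows
(residues 1–10, 11–20) gets occupancy clamp(0.5 + (mean propensity − 0.36) × 12).

Two design choices deserve explanation, both made once, by simulation of the
design itself, before the generator was frozen:

* **Two fixed half-peptide segments** rather than one scanned window: with
  n = 20 peptides per set, the variance of a set's mean helix-residue count
  is dominated by composition sampling; two independent segments per peptide
  halve it, which is what makes the expected alphabet ordering
  (GADVE > GA(D/E)V > GADV) reproducible across small replicates.
* **Nearly equal weak-former propensities with strong E/L**: the occupancy
  rule then thresholds essentially on the number of strong helix formers in
  a window, and the threshold (0.36) sits in the gap between one- and
  two-strong-former window means. This maximizes the statistical separation
  between alphabets that differ in glutamate frequency. The cost is
  absolute realism: under this map the four-letter sets form almost no
  helix, so the experiment reproduces the *ordering* of alphabets and the
  sign of the solubility trade-off, not absolute per-set means from any
  physical simulation.

## Numerical choices and degenerate inputs

* Window arithmetic: an analysis window of w ns selects the final
  round(1000·w / spacing_ps) frames; requesting more frames than exist is an
  error, not a truncation.
* Superposition uses SVD with a determinant guard (reflections are never
  returned); degenerate (collinear) point sets are rejected. The
  quaternion-based solver in the test suite is the independent oracle.
* The H-bond boundary comparisons carry a 1e-9 guard band so that
  constructed boundary geometries (angle exactly 120°, distance exactly
  3.5 Å) classify by their nominal values rather than by floating-point
  representation noise.
* Coincident atoms in the surface stage are flagged and excluded (zero
  area, no occlusion) rather than silently double-counted.
* Chains shorter than three residues carry no assignable pattern and label
  as `-`; the chain-start residue has no amide donor.
* Sequence generation derives one RNG substream per peptide from the master
  seed, so enlarging a library never reshuffles already-generated peptides.

## Problem sizes used in the shipped analyses

The shipped scripts and checks run 20 peptides per set at 2000 frames
(20 seeded replicates for the ordering experiment), surface areas on every
50th frame, and 5000-frame noise scaffolds for the RMSF analytics — sizes
chosen so the full campaign completes in minutes on one core while keeping
every statistical claim inside stated error bounds. The same code paths
accept production-scale input (e.g. 20,000-frame windows from 200 ns runs
written every 0.5 ps) unchanged.

## Known limitations

* Sheet statistics are limited to per-frame E/B labels; no ladder/sheet
  bookkeeping is aggregated, because 20-mers do not stably retain sheets.
* The assigner targets the classic pattern rules; variant-specific details
  (π-helix priority conventions, bulge edge cases) can shift one or two
  residues at helix termini relative to other implementations.
* The builder covers the six residue types of these alphabets plus charged
  termini; it is not a general PDB chemistry engine.
* Whether production H-bond averages should count backbone-only donors, or
  PSA should count polar hydrogens, are protocol choices; both switches are
  exposed and the defaults are stated above.
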