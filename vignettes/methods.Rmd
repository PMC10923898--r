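---
title: "Methods: structure-derived features for phase-separation prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-derived features for phase-separation prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspredict)
```

## The problem

Phase-separating proteins (PSPs) form liquid-like biomolecular
condensates through many weak multivalent contacts. In the
stickers-and-spacers picture, "stickers" are the interaction-bearing
elements and "spacers" the intervening material. Sequence-only
predictors recognise PSPs whose multivalency comes from intrinsically
disordered regions (IDRs) but perform poorly on well-folded PSPs whose
stickers are patches on the domain surface. `pspredict` closes that gap
by reading an AlphaFold-style structure model and deriving features
from the *structured superficial* part of the protein — the solvent
exposed residues outside all IDRs — including explicit detection of
charged surface sticker clusters.

## Pipeline

For each single-chain PDB model (pLDDT in the B-factor column):

1. **Disorder calling.** A residue is disordered when pLDDT < 50
   (strict). Residues assigned helix or sheet by the secondary-structure
   module are forced ordered. The mask is then refined: (i) *smoothing*
   to a fixpoint — runs of up to 3 residues surrounded by the opposite
   state flip, disordered-to-ordered conversions first within each pass
   (the sentence order of the refinement recipe; the other order is
   available via `smooth_order`); (ii) *bridging* — ordered runs of up
   to 10 residues flanked on both sides by disordered runs of at least
   20 become disordered, in a single pass after the smoothing fixpoint
   (we decided against cascading bridges because the recipe describes
   one conversion step); (iii) *pruning* — disordered runs shorter than
   20 are dropped. Runs touching a chain terminus have one flank only
   and are never smoothed or bridged. A protein with at least one
   surviving IDR is an "ID" protein, otherwise "noID".

2. **Secondary structure.** An internal Kabsch–Sander implementation:
   amide hydrogens are placed 1 Å from N anti-parallel to the preceding
   carbonyl; the hydrogen-bond energy is
   E = 0.084 (1/rON + 1/rCH − 1/rOH − 1/rCN) × 332 kcal/mol with bonds
   below −0.5 kcal/mol; H/G/I helices from consecutive n-turns, B/E
   bridges and ladders, T turns, S bends (>70°), "-" otherwise; the
   3-class collapse is helix = {H,G,I}, sheet = {B,E}, loop = the rest.
   An external `mkdssp` binary can be substituted (`ss_backend`);
   downstream code consumes only the 3-class states, which are robust
   to implementation differences at the 8-state level. No DSSP binary
   ships with the supported environment, so the internal assigner is
   the default.

3. **Surface.** Shrake–Rupley SASA on heavy atoms (probe 1.4 Å, 960
   deterministic golden-spiral points per atom), normalised per residue
   by the theoretical maximum ASA of Tien et al. (2013)
   (`max_asa_table = "sander1994"` selects the older table; the
   upstream normalisation choice is not documented, and the 25%
   threshold is robust to it). A residue is exposed when RSA > 0.25
   (strict). SSUP = exposed ∩ non-IDR. Before sampling, coordinates are
   rotated into a canonical principal-axes frame with a deterministic
   sign convention, which makes the finite point sampling exactly
   invariant under rigid-body motion of the input — a property the test
   suite asserts at 1e-6.

4. **Charged stickers.** For every SSUP residue, the net charge index
   (NCI) counts positive SSUP residues (K, R by default; histidine is
   excluded at pH 7 and configurable) minus negative ones (D, E) within
   14 Å; distances are Cα–Cα (an any-heavy-atom metric is available),
   and a charged residue counts toward its own NCI. Residues with
   |NCI| > 3 are candidates. Candidates are clustered by agglomerative
   centroid linkage on Cα coordinates, cutting at the same 14 Å. Each
   cluster's sign is its members' majority NCI sign (ties: sign of the
   summed NCI; exact zero-sum clusters are discarded with a warning).
   Sticker count, pair count (min of positive and negative cluster
   counts) and their SSUP-normalised frequencies are the sticker
   features. `threshold_scan()` reproduces the cutoff selection: the
   distance in 10–20 Å maximising the fraction of proteins with ≥3
   stickers, ties to the smaller distance; 14 Å is the shipped default.
   With an empty SSUP the sticker frequencies are 0, not missing — no
   sticker is geometrically possible, and a defined zero keeps the
   feature usable for every structured protein.

5. **Features.** Per region (IDR and SSUP): the 20 amino-acid
   fractions, 15 property-group proportions, mean normalised
   Kyte–Doolittle hydropathy ((KD + 4.5)/9), mean Zimmerman (1968)
   polarity (the upstream polarity reference is unnamed; Zimmerman is
   the conventional choice and the scale is injectable), isoelectric
   point (Henderson–Hasselbalch bisection to 1e-3 pH with an
   ExPASy-style pKa set) and molecular weight (average residue masses
   plus one water). Plus IDR length and IDR fraction of the protein,
   the two sticker frequencies, and optionally the phosphosite
   frequency (distinct sites / length; human model only). IDR features
   of proteins without IDRs are *missing*, never zero — zero is a
   meaningful composition value — and `ignore_idr = TRUE` nulls them
   for every protein, the switch for modular-domain proteins whose
   incidental IDRs mislead the model. 83 features with the phosphosite
   column, 82 without.

6. **Classifier.** Min-max scaling fitted on training rows (missing
   values ignored and propagated). Ten gradient-boosted tree models,
   each trained on all positives plus a fresh negative subsample of
   twice the positive count, with inverse-frequency sample weights over
   the three classes (ID-PSP, noID-PSP, non-PSP); the prediction is the
   member mean. The boosted trees are an in-package Rcpp implementation
   of the standard second-order logistic boosting algorithm (the nine
   conventional hyperparameters; missing values routed through learned
   default directions) because no gradient-boosting library exists in
   the supported environment. Hyperparameters are tuned by random
   search over conventional wide bounds (the published search ranges
   are not available) with stratified 5-fold cross-validation whose
   objective is the mean AUROC for ID-PSPs vs non-PSPs; within each
   fold the validation sets stay fixed while ten negative training
   subsets are drawn. The scaler is fitted inside each fold by default
   (`scale_mode = "full"` reproduces a single whole-training-set fit).
   Seed 42 everywhere; two model variants (with/without the phosphosite
   feature) mirror the human/generic split.

7. **Evaluation.** Trapezoidal AUROC (equal to the Mann–Whitney
   statistic; asserted exhaustively in tests), step-wise
   (average-precision) AUPRC, the decision threshold from the ROC point
   nearest (0, 1) (ties to the higher-specificity point; predictions
   use score ≥ threshold — the comparison direction is not specified
   upstream and is documented here), MCC/F1/sensitivity/specificity/
   accuracy/FPR/FNR, and the MLO protocol: membraneless-organelle
   membership as weak positives, training positives excluded,
   ID/noID split by the pipeline's own IDR call.

## What the synthetic fixtures emulate — and what they do not

`make_structure()` builds ideal-geometry backbones (helix φ=−57°,
ψ=−47°; extended φ=−135°, ψ=135°; coil = self-avoiding draws from the
polyproline-II region, clash floor 3.2 Å) with controllable pLDDT, so
disorder calling, secondary structure and the IDR arithmetic have exact
ground truth. `make_sticker_toy()` places charged residues in jittered
4 Å rings spaced ≥40 Å apart: every residue is exposed, every blob is
one sticker, and the expected counts are the construction parameters.
`make_labeled_features()` plants a mean shift on SSUP-derived columns
of an otherwise iid Gaussian table; at the default effect sizes it
calibrates the ensemble (null AUROC ≈ 0.5, effect 3 ⇒ AUROC ≥ 0.95 at
n = 200/400 — sizes chosen to match the recoverable-signal check).

These articles are geometric, not physical: no side chains beyond the
feature tables' needs, no realistic packing, no correlated feature
structure. A green suite therefore establishes the *algorithms* —
thresholds, refinement, clustering, weighting, scoring — not
biological accuracy of the published headline AUCs, which would require
the full AlphaFold human proteome and curated PSP/MLO datasets that an
offline environment cannot obtain. The two published worked examples
(SERPINB4: 10 charged stickers; PGM1: 11) are wired into the acceptance
test and the report script and run whenever the two AlphaFold v4 files
are placed under `inst/extdata/alphafold/`.

## Numerical choices and degenerate inputs

* pLDDT read from the B-factor of any atom; intra-residue disagreement
  beyond 1e-6 falls back to the Cα value with a warning (AlphaFold
  files are uniform per residue).
* Proteins with length ≤ 100 or ≥ 2700 are excluded by
  `length_eligible()`; AlphaFold fragments long proteins rather than
  modelling them whole, and we reject rather than stitch.
* Selenomethionine and other modified residues error by default; a
  3-to-1 override (`extra_aa3 = c(MSE = "M")`) opts in explicitly.
* Empty SSUP: composition features missing, sticker frequencies 0.
* Constant feature columns scale to 0; test-set values outside the
  training range are not clipped.
* MCC is defined as 0 when a confusion-matrix marginal is empty.
* pI bisection tolerance 1e-3 pH on [0, 14].
* Centroid-linkage ties resolve to the first minimal pair in cluster
  order; the acceptance oracle uses the same deterministic rule
  recomputed from scratch.

## Known limitations

* The 8-state secondary-structure assignment approximates DSSP at the
  edges (ladder bookkeeping, polyproline-II); only the 3-class collapse
  feeds the pipeline.
* SASA is heavy-atom only (AlphaFold emits no hydrogens) and the
  normalisation table is a configuration choice, not a reproduction of
  PSAIA.
* The boosted-tree implementation is exact-greedy and single-threaded;
  it is not intended for datasets beyond the tens of thousands of rows
  this task needs.
* Random search replaces the original sequential model-based optimiser;
  with the published 1000-trial budget the difference is conventional
  wisdom-level small, but tuned optima are not expected to match
  bit-for-bit.
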