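# pspredict

Structure-based prediction of phase-separating proteins (PSPs).

Most sequence-based predictors of liquid–liquid phase separation lean
on intrinsically disordered regions (IDRs) and miss well-folded PSPs
whose multivalency lives on the domain surface. `pspredict` reads
AlphaFold-style structure models (single chain, per-residue pLDDT in
the PDB B-factor column) and derives *structure-aware* features:

* **IDRs** from pLDDT < 50, filtered by secondary structure and refined
  by smoothing (runs ≤ 3), bridging (ordered gaps ≤ 10 between IDRs
  ≥ 20) and pruning (< 20);
* **SSUP**, the structured superficial region: residues with relative
  solvent accessibility > 25% (Shrake–Rupley SASA / max-ASA) outside
  all IDRs;
* **charged stickers**: for each SSUP residue the net charge index
  NCI(i) = #{positive SSUP residues within 14 Å} − #{negative ones};
  residues with |NCI| > 3 are clustered by centroid linkage on Cα
  coordinates (cut at 14 Å) into positive/negative sticker clusters,
  yielding sticker and sticker-pair counts and SSUP-normalised
  frequencies;
* a **feature vector** (~83 features: per-region composition, group
  proportions, hydropathy, polarity, pI, molecular weight, IDR extent,
  sticker frequencies, optional phosphosite frequency), scored by an
  ensemble of ten gradient-boosted tree models trained on repeated 2:1
  negative subsamples with inverse-frequency class weights; the PS
  score is the member mean, in [0, 1].

Evaluation utilities (ROC/PRC, nearest-top-left thresholding, MCC and
friends, the MLO weak-label protocol) and a synthetic fixture generator
with analytically known ground truth are included. See
`vignettes/methods.Rmd` for the full model description and design
decisions.

## Worked example

```r
library(pspredict)

# a synthetic protein: 60-residue helix, 30-residue low-confidence coil,
# 40-residue helix -- and a surface toy with 2 positive + 1 negative
# charge clusters
m <- make_structure(list(
  list(length = 60, geometry = "helix", plddt = 90),
  list(length = 30, geometry = "coil",  plddt = 40),
  list(length = 40, geometry = "helix", plddt = 85)), id = "demo", seed = 42)
analyze_structure(m)
#> <structure_analysis> demo (ID): 130 aa, 1 IDR(s), |SSUP| = 100, 0 sticker(s) (0 pair(s))

toy <- make_sticker_toy(2, 1, 5, 50, seed = 7)
an <- analyze_structure(toy)
an$stickers$summary[c("n_pos", "n_neg", "n_pairs")]
#> $n_pos
#> [1] 2
#> $n_neg
#> [1] 1
#> $n_pairs
#> [1] 1
```

The demo protein is an "ID" protein whose 30 low-confidence coil
residues survive refinement as one IDR (positions 61–90); the toy's
three charge blobs come back as exactly two positive and one negative
sticker (one sticker pair). Training and scoring:

```r
d <- make_labeled_features(200, 400, effect_size = 3, seed = 42)
d <- split_dataset(d, seed = 42)                  # 1:1 stratified
ens <- train_ensemble(d[d$split == "train", ], seed = 42)
sc <- predict_ensemble(ens, d[d$split == "test", ])$score
auroc(sc, d$label[d$split == "test"] != "non-PSP")
#> [1] 1
```

Batch use mirrors the R API: `cmd_features()`, `cmd_train()`,
`cmd_predict()`, `cmd_eval()`, `cmd_fixtures()` and the dispatcher
`pspredict_main()` (subcommands `features`, `predict`, `train`, `eval`,
`fixtures`, `threshold-scan`) read PDB directories and write
CSV/JSON/BED, with a config snapshot next to every output.

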