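## features: residue-level composition, physicochemical scores, IDR extent,
## phosphosite frequency, and assembly of the full feature vector.

#' Extract the sequence of a residue region
#'
#' @param model a `protein_model`.
#' @param region a `segment_set` or an integer vector of residue indices.
#' @return Amino-acid string (possibly empty).
#' @export
region_sequence <- function(model, region) {
  idx <- if (inherits(region, "segment_set")) segment_residues(region)
         else as.integer(region)
  if (!length(idx)) return("")
  stopifnot(all(idx >= 1 & idx <= model$n))
  paste(strsplit(model$sequence, "")[[1]][idx], collapse = "")
}

#' Amino-acid fractions
#'
#' Fraction of each of the 20 standard residues in a sequence; all-NA for
#' an empty sequence (missing region).
#'
#' @param seq amino-acid string.
#' @return Named numeric vector of length 20 (names `fraction_<aa>`).
#' @export
aa_fractions <- function(seq) {
  out <- setNames(rep(NA_real_, 20), paste0("fraction_", AA1))
  if (!nchar(seq)) return(out)
  aa <- strsplit(seq, "")[[1]]
  if (!all(aa %in% AA1)) stop("non-standard residue in sequence")
  tab <- table(factor(aa, levels = AA1))
  out[] <- as.numeric(tab) / length(aa)
  out
}

#' Residue-group proportions
#'
#' Proportion of residues belonging to each of the fifteen property
#' groups (see [aa_groups()]); groups overlap, so proportions do not sum
#' to one.
#'
#' @param seq amino-acid string.
#' @param groups group table, default [aa_groups()].
#' @return Named numeric vector of length 15 (names `group_<name>`).
#' @export
group_fractions <- function(seq, groups = aa_groups()) {
  out <- setNames(rep(NA_real_, length(groups)),
                  paste0("group_", names(groups)))
  if (!nchar(seq)) return(out)
  aa <- strsplit(seq, "")[[1]]
  out[] <- vapply(groups, function(g) mean(aa %in% g), numeric(1))
  out
}

#' Mean normalised Kyte-Doolittle hydropathy
#'
#' Per-residue hydropathy is (KD + 4.5) / 9, mapping the Kyte-Doolittle
#' scale onto \[0, 1\]; the feature is the mean over the region.
#'
#' @param seq amino-acid string.
#' @return Scalar in \[0, 1\], `NA` for empty input.
#' @export
mean_hydropathy <- function(seq) {
  if (!nchar(seq)) return(NA_real_)
  aa <- strsplit(seq, "")[[1]]
  mean((KYTE_DOOLITTLE[aa] + 4.5) / 9)
}

#' Mean polarity (Zimmerman scale)
#'
#' @param seq amino-acid string.
#' @param scale named per-residue polarity values, default Zimmerman 1968.
#' @return Scalar mean polarity, `NA` for empty input.
#' @export
mean_polarity <- function(seq, scale = ZIMMERMAN_POLARITY) {
  if (!nchar(seq)) return(NA_real_)
  aa <- strsplit(seq, "")[[1]]
  mean(scale[aa])
}

peptide_charge <- function(counts, ph, pka = PKA_SET) {
  pos <- 1 / (1 + 10^(ph - pka$nterm))
  neg <- -1 / (1 + 10^(pka$cterm - ph))
  for (a in names(pka$positive))
    pos <- pos + counts[a] / (1 + 10^(ph - pka$positive[[a]]))
  for (a in names(pka$negative))
    neg <- neg - counts[a] / (1 + 10^(pka$negative[[a]] - ph))
  unname(pos + neg)
}

#' Isoelectric point of a region treated as a peptide
#'
#' Henderson-Hasselbalch net charge (side chains plus one amino and one
#' carboxy terminus, ExPASy-style pKa set) solved for zero by bisection
#' to 1e-3 pH.
#'
#' @param seq amino-acid string.
#' @return pH value, `NA` for empty input.
#' @export
isoelectric_point <- function(seq) {
  if (!nchar(seq)) return(NA_real_)
  aa <- strsplit(seq, "")[[1]]
  counts <- table(factor(aa, levels = AA1))
  lo <- 0; hi <- 14
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (peptide_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular weight of a region treated as a peptide
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param seq amino-acid string.
#' @return Mass in daltons, `NA` for empty input.
#' @export
molecular_weight <- function(seq) {
  if (!nchar(seq)) return(NA_real_)
  aa <- strsplit(seq, "")[[1]]
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

#' IDR extent features
#'
#' Total residues covered by IDRs and that total as a fraction of the
#' protein length; both missing for a protein without IDRs.
#'
#' @param idrs a `segment_set`.
#' @param n protein length.
#' @return Named numeric vector `c(idr_length=, idr_percent=)`.
#' @export
idr_extent <- function(idrs, n) {
  if (!nrow(idrs))
    return(c(idr_length = NA_real_, idr_percent = NA_real_))
  len <- sum(idrs[, "end"] - idrs[, "start"] + 1)
  c(idr_length = len, idr_percent = len / n)
}

#' Phosphosite frequency
#'
#' Number of distinct phosphorylation sites recorded for a protein,
#' divided by its sequence length; 0 when the protein is absent from the
#' table. Sites beyond the parsed length (isoform mismatches) are counted
#' but trigger a warning, mirroring a naive identifier join.
#'
#' @param protein_id identifier to look up.
#' @param length protein length.
#' @param phos_table data.frame with columns `id` and `position`, or NULL.
#' @return Scalar frequency.
#' @export
phos_frequency <- function(protein_id, length, phos_table) {
  if (is.null(phos_table)) return(0)
  sites <- unique(phos_table$position[phos_table$id == protein_id])
  if (any(sites > length))
    warning("phosphosite beyond sequence length for ", protein_id,
            " (isoform mismatch?)")
  length(sites) / length
}

region_features <- function(seq, suffix) {
  v <- c(aa_fractions(seq), group_fractions(seq),
         hydropathy = mean_hydropathy(seq),
         polarity = mean_polarity(seq),
         pI = isoelectric_point(seq),
         mw = molecular_weight(seq))
  setNames(v, paste0(names(v), "_", suffix))
}

#' Feature schema
#'
#' The ordered feature-name list shared by every protein in a run: 39
#' composition/physicochemical features per region (IDR and SSUP), IDR
#' extent, sticker frequencies, and optionally the phosphosite frequency
#' (83 features with it, 82 without).
#'
#' @param use_phos include `phos_frequency`?
#' @return Character vector of feature names.
#' @export
feature_schema <- function(use_phos = FALSE) {
  per_region <- c(paste0("fraction_", AA1), paste0("group_", names(aa_groups())),
                  "hydropathy", "polarity", "pI", "mw")
  c(paste0(per_region, "_idr"), paste0(per_region, "_ssup"),
    "idr_length", "idr_percent", "sticker_ssup", "sticker_pair_ssup",
    if (use_phos) "phos_frequency")
}

#' Assemble the feature vector for one protein
#'
#' IDR-region features are missing (NA, never 0) for proteins without
#' IDRs, or for every protein when `ignore_idr = TRUE` (the option that
#' treats modular-domain proteins with incidental IDRs as structure-only).
#' SSUP composition features are missing when the SSUP is empty, but the
#' sticker frequencies are then 0 (no stickers are geometrically
#' possible).
#'
#' @param model a `protein_model`.
#' @param idrs a `segment_set` of refined IDRs.
#' @param ssup integer vector of SSUP residues.
#' @param sticker_summary list from [summarize_stickers()].
#' @param phos_table optional phosphosite table (`id`, `position`).
#' @param use_phos include the phosphosite frequency feature?
#' @param ignore_idr force all IDR-derived features to missing?
#' @return Named numeric vector following [feature_schema()].
#' @export
build_feature_vector <- function(model, idrs, ssup, sticker_summary,
                                 phos_table = NULL, use_phos = FALSE,
                                 ignore_idr = FALSE) {
  idr_seq <- if (ignore_idr) "" else region_sequence(model, idrs)
  ssup_seq <- region_sequence(model, ssup)
  out <- c(region_features(idr_seq, "idr"),
           region_features(ssup_seq, "ssup"),
           if (ignore_idr) c(idr_length = NA_real_, idr_percent = NA_real_)
           else idr_extent(idrs, model$n),
           sticker_ssup = sticker_summary$freq_sticker,
           sticker_pair_ssup = sticker_summary$freq_pair)
  if (use_phos)
    out <- c(out, phos_frequency = phos_frequency(model$id, model$n,
                                                  phos_table))
  stopifnot(identical(names(out), feature_schema(use_phos)))
  out
}
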