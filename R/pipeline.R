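## pipeline: run configuration and the per-protein / per-directory
## orchestration from PDB file to feature vector.

#' Run configuration
#'
#' All tunable thresholds of the pipeline with their published defaults:
#' sticker neighbourhood and clustering cutoff 14 A, RSA exposure cutoff
#' 25%, pLDDT disorder cutoff 50, |NCI| cutoff 3, charged sets K/R vs
#' D/E, seed 42.
#'
#' @param distance_threshold sticker neighbourhood / clustering cutoff, A.
#' @param rsa_cutoff exposure threshold on RSA.
#' @param plddt_cutoff disorder threshold on pLDDT.
#' @param nci_cutoff strict threshold on |NCI|.
#' @param positive_set,negative_set charged residue sets.
#' @param nci_metric `"ca"` or `"any"` (heavy-atom) neighbour metric.
#' @param ss_backend `"internal"` or `"external"` DSSP.
#' @param smooth_order IDR smoothing pass order, see [refine_mask()].
#' @param max_asa_table RSA normalisation table.
#' @param sasa_probe,sasa_points Shrake-Rupley parameters.
#' @param use_phos include the phosphosite feature (human model)?
#' @param ignore_idr null out IDR features for all proteins?
#' @param seed RNG seed for training-time sampling.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(distance_threshold = 14, rsa_cutoff = 0.25,
                       plddt_cutoff = 50, nci_cutoff = 3,
                       positive_set = c("K", "R"),
                       negative_set = c("D", "E"),
                       nci_metric = "ca",
                       ss_backend = "internal",
                       smooth_order = "disorder_first",
                       max_asa_table = "tien2013",
                       sasa_probe = 1.4, sasa_points = 960,
                       use_phos = FALSE, ignore_idr = FALSE, seed = 42) {
  structure(list(distance_threshold = distance_threshold,
                 rsa_cutoff = rsa_cutoff, plddt_cutoff = plddt_cutoff,
                 nci_cutoff = nci_cutoff, positive_set = positive_set,
                 negative_set = negative_set, nci_metric = nci_metric,
                 ss_backend = ss_backend, smooth_order = smooth_order,
                 max_asa_table = max_asa_table, sasa_probe = sasa_probe,
                 sasa_points = sasa_points, use_phos = use_phos,
                 ignore_idr = ignore_idr, seed = seed),
            class = "run_config")
}

#' Analyse one structure end to end
#'
#' Parses (if given a path), assigns secondary structure, calls IDRs,
#' computes the surface profile, derives the SSUP, and detects stickers.
#'
#' @param x a `protein_model` or a PDB file path.
#' @param config a [run_config()].
#' @return List of class `structure_analysis` with fields `model`, `ss`,
#'   `idrs`, `surface`, `ssup`, `stickers`, `protein_type`.
#' @export
analyze_structure <- function(x, config = run_config()) {
  model <- if (inherits(x, "protein_model")) x else read_pdb(x)
  ss <- assign_ss(model, backend = config$ss_backend)
  idrs <- find_idrs(model, ss, config)
  surf <- surface_profile(model, config)
  ssup <- derive_ssup(surf$exposed, idrs, model$n)
  st <- sticker_profile(model, ssup, config)
  structure(list(model = model, ss = ss, idrs = idrs, surface = surf,
                 ssup = ssup, stickers = st,
                 protein_type = classify_protein(idrs)),
            class = "structure_analysis")
}

#' @export
print.structure_analysis <- function(x, ...) {
  cat(sprintf(
    "<structure_analysis> %s (%s): %d aa, %d IDR(s), |SSUP| = %d, %d sticker(s) (%d pair(s))\n",
    x$model$id, x$protein_type, x$model$n, nrow(x$idrs), length(x$ssup),
    x$stickers$summary$n_total, x$stickers$summary$n_pairs))
  invisible(x)
}

#' Feature vector from an analysed structure
#'
#' @param analysis a `structure_analysis`.
#' @param phos_table optional phosphosite table.
#' @param config a [run_config()].
#' @return Named numeric feature vector.
#' @export
analysis_features <- function(analysis, phos_table = NULL,
                              config = run_config()) {
  build_feature_vector(analysis$model, analysis$idrs, analysis$ssup,
                       analysis$stickers$summary, phos_table,
                       use_phos = config$use_phos,
                       ignore_idr = config$ignore_idr)
}

#' Feature matrix for a set of structures
#'
#' Runs the full pipeline over PDB files or pre-built models. Proteins
#' failing the length-eligibility rule or erroring during analysis are
#' dropped with a warning (batch robustness); the returned attribute
#' `failures` records them.
#'
#' @param inputs character vector of PDB paths, or list of
#'   `protein_model` objects.
#' @param phos_table optional phosphosite table.
#' @param config a [run_config()].
#' @param check_length apply the 100 < N < 2700 eligibility filter?
#' @return data.frame: `id`, `protein_type`, `n_ssup`, `n_stickers`, then
#'   one column per feature in [feature_schema()].
#' @export
compute_feature_matrix <- function(inputs, phos_table = NULL,
                                   config = run_config(),
                                   check_length = TRUE) {
  rows <- list()
  failures <- character(0)
  for (x in inputs) {
    id <- if (inherits(x, "protein_model")) x$id else basename(x)
    res <- tryCatch({
      an <- analyze_structure(x, config)
      if (check_length && !length_eligible(an$model))
        stop("length ", an$model$n, " outside (100, 2700)")
      fv <- analysis_features(an, phos_table, config)
      c(list(id = an$model$id, protein_type = an$protein_type,
             n_ssup = length(an$ssup),
             n_stickers = an$stickers$summary$n_total), as.list(fv))
    }, error = function(e) {
      warning("skipping ", id, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) failures <- c(failures, id)
    else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("no protein could be analysed")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "failures") <- failures
  out
}
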