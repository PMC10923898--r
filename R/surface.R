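## surface: Shrake-Rupley SASA, relative solvent accessibility, exposure
## calls, and the SSUP (structured superficial) residue set.

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley SASA on heavy atoms (AlphaFold models carry no
#' hydrogens), probe radius 1.4 A, deterministic golden-spiral test
#' points, summed per residue.
#'
#' Atom coordinates are first moved into a canonical frame (principal
#' axes of the atom cloud, deterministic sign convention) so that the
#' finite point sampling is exactly invariant under rigid-body motion of
#' the input structure.
#'
#' @param model a `protein_model`.
#' @param probe probe radius in angstrom (1.4).
#' @param n_points sphere test points per atom (960).
#' @param vdw named van der Waals radius set by element.
#' @param canonicalize rotate into the canonical frame first (TRUE).
#' @return Numeric vector of per-residue SASA (A^2).
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960,
                         vdw = VDW_RADII, canonicalize = TRUE) {
  a <- model$atoms
  if (!all(seq_len(model$n) %in% a$residue))
    stop("residue without atoms")
  r <- vdw[a$element]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(a$element[is.na(r)]), collapse = ", "))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (canonicalize) xyz <- canonical_frame(xyz)
  atom_sasa <- .sasa_cpp(xyz, unname(r), probe, as.integer(n_points))
  as.numeric(tapply(atom_sasa, factor(a$residue, levels = seq_len(model$n)),
                    sum, default = 0))
}

## principal-axis frame with a deterministic sign convention: makes the
## golden-spiral SASA sampling independent of the input orientation
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(xyz)
  centred <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(stats::cov(centred), symmetric = TRUE)$vectors
  proj <- centred %*% ev
  for (k in 1:3) {
    s <- sum(proj[, k]^3)
    if (s < 0) {
      ev[, k] <- -ev[, k]
      proj[, k] <- -proj[, k]
    }
  }
  # right-handed frame
  if (det(ev) < 0) proj[, 3] <- -proj[, 3]
  proj
}

#' Relative solvent accessibility
#'
#' RSA is per-residue SASA divided by the residue-type maximum ASA from a
#' published normalisation table.
#'
#' @param sasa numeric per-residue SASA.
#' @param sequence one-letter amino-acid string of matching length.
#' @param table `"tien2013"` (theoretical, default) or `"sander1994"`.
#' @return Numeric vector of RSA values (unbounded above 1 for unusually
#'   exposed conformations).
#' @export
compute_rsa <- function(sasa, sequence, table = c("tien2013", "sander1994")) {
  table <- match.arg(table)
  aa <- strsplit(sequence, "")[[1]]
  if (length(sasa) != length(aa))
    stop("sasa length != sequence length")
  mx <- MAX_ASA[[table]][aa]
  if (anyNA(mx))
    stop("unknown amino acid: ", paste(unique(aa[is.na(mx)]), collapse = ","))
  unname(sasa / mx)
}

#' Exposed-residue mask
#'
#' A residue is exposed when its RSA is strictly greater than the cutoff
#' (default 25%).
#'
#' @param rsa numeric RSA vector.
#' @param cutoff exposure threshold (0.25).
#' @return Logical vector.
#' @export
exposed_mask <- function(rsa, cutoff = 0.25) {
  stopifnot(all(is.finite(rsa)), all(rsa >= 0))
  rsa > cutoff
}

#' Derive the SSUP residue set
#'
#' SSUP (structured superficial region) is the intersection of the
#' exposed set (RSA > 25%) with the non-IDR residues.
#'
#' @param exposed logical exposure mask of length `n`.
#' @param idrs a `segment_set` of IDRs.
#' @param n protein length.
#' @return Sorted integer vector of SSUP residue indices.
#' @export
derive_ssup <- function(exposed, idrs, n) {
  stopifnot(length(exposed) == n)
  in_idr <- mask_from_segments(idrs, n)
  which(exposed & !in_idr)
}

#' Full surface profile for one protein
#'
#' @param model a `protein_model`.
#' @param config a [run_config()].
#' @return List with `sasa`, `rsa`, `exposed` per-residue vectors.
#' @export
surface_profile <- function(model, config = run_config()) {
  sasa <- compute_sasa(model, probe = config$sasa_probe,
                       n_points = config$sasa_points)
  rsa <- compute_rsa(sasa, model$sequence, table = config$max_asa_table)
  list(sasa = sasa, rsa = rsa,
       exposed = exposed_mask(rsa, config$rsa_cutoff))
}
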