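## disorder: pLDDT-based IDR calling, secondary-structure filtering, and
## the smoothing / bridging / length-pruning refinement.

#' Raw disorder mask from pLDDT
#'
#' A residue is disordered when its pLDDT is strictly below the cutoff
#' (default 50).
#'
#' @param plddt numeric vector of per-residue pLDDT scores in \[0, 100\].
#' @param cutoff disorder threshold, default 50.
#' @return Logical vector, `TRUE` = disordered.
#' @export
raw_disorder_mask <- function(plddt, cutoff = 50) {
  stopifnot(all(is.finite(plddt)), all(plddt >= 0 & plddt <= 100))
  plddt < cutoff
}

#' Remove helix/sheet residues from a disorder mask
#'
#' Residues assigned helix or sheet secondary structure cannot be part of
#' an IDR regardless of their pLDDT.
#'
#' @param mask logical disorder mask.
#' @param states3 character vector over `c("helix","sheet","loop")`.
#' @return Filtered logical mask.
#' @export
filter_secondary_structure <- function(mask, states3) {
  if (length(mask) != length(states3))
    stop("mask length (", length(mask), ") != states length (",
         length(states3), ")")
  mask & !(states3 %in% c("helix", "sheet"))
}

## run-length view of a logical mask; a plain list keeps this cheap for
## the exhaustive property sweeps
runs_of <- function(mask) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  list(value = r$values, start = end - r$lengths + 1L, end = end,
       length = r$lengths, n = length(end))
}

#' Refine a disorder mask into IDR segments
#'
#' Three phases, in order: (1) smoothing to fixpoint -- short runs of up
#' to `smooth_max` residues flanked on both sides by the opposite state
#' flip to that state (disordered-to-ordered conversions first within each
#' pass, then ordered-to-disordered, order configurable); (2) bridging --
#' ordered runs of up to `bridge_max` residues flanked by two disordered
#' runs of at least `min_len` residues become disordered (single pass);
#' (3) pruning -- disordered runs shorter than `min_len` are dropped.
#' Runs touching a chain terminus have only one flank and are never
#' smoothed or bridged.
#'
#' @param mask logical disorder mask.
#' @param smooth_max longest run convertible during smoothing (3).
#' @param bridge_max longest ordered run convertible by bridging (10).
#' @param min_len minimum IDR length kept (20); also the minimum flank for
#'   bridging.
#' @param smooth_order `"disorder_first"` (default) or `"order_first"`:
#'   which short-run conversion is applied first within a smoothing pass.
#' @return Object of class `segment_set`: integer matrix with columns
#'   `start`, `end` (1-based inclusive, sorted, non-overlapping).
#' @export
refine_mask <- function(mask, smooth_max = 3, bridge_max = 10, min_len = 20,
                        smooth_order = c("disorder_first", "order_first")) {
  smooth_order <- match.arg(smooth_order)
  stopifnot(is.logical(mask), !anyNA(mask))
  n <- length(mask)

  flip_short <- function(mask, state, maxlen) {
    # flip runs of `state` with length <= maxlen and both flanks present
    r <- runs_of(mask)
    idx <- seq_len(r$n)
    conv <- which(r$value == state & r$length <= maxlen &
                    idx > 1 & idx < r$n)
    for (k in conv) mask[r$start[k]:r$end[k]] <- !state
    mask
  }

  # phase 1: smoothing to fixpoint
  repeat {
    before <- mask
    if (smooth_order == "disorder_first") {
      mask <- flip_short(mask, TRUE, smooth_max)
      mask <- flip_short(mask, FALSE, smooth_max)
    } else {
      mask <- flip_short(mask, FALSE, smooth_max)
      mask <- flip_short(mask, TRUE, smooth_max)
    }
    if (identical(mask, before)) break
  }

  # phase 2: single bridging pass
  r <- runs_of(mask)
  if (r$n >= 3) {
    for (k in 2:(r$n - 1)) {
      if (!r$value[k] && r$length[k] <= bridge_max &&
          r$value[k - 1] && r$length[k - 1] >= min_len &&
          r$value[k + 1] && r$length[k + 1] >= min_len) {
        mask[r$start[k]:r$end[k]] <- TRUE
      }
    }
  }

  # phase 3: prune short IDRs
  r <- runs_of(mask)
  keep <- which(r$value & r$length >= min_len)
  segment_set(r$start[keep], r$end[keep], n)
}

#' Segment set constructor
#'
#' Sorted, non-overlapping, 1-based inclusive residue intervals.
#'
#' @param start,end integer vectors of equal length.
#' @param n protein length the segments refer to (attribute `n`).
#' @return Integer matrix of class `segment_set` with columns start/end.
#' @export
segment_set <- function(start = integer(0), end = integer(0), n = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), all(start <= end),
            all(start >= 1))
  if (length(start) > 1) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (any(start[-1] <= end[-length(end)])) stop("overlapping segments")
  }
  structure(cbind(start = start, end = end), n = as.integer(n),
            class = c("segment_set", "matrix", "array"))
}

#' Expand a segment set back to a logical mask
#'
#' @param segments a `segment_set`.
#' @param n protein length; defaults to the segment set's `n` attribute.
#' @return Logical vector of length `n`.
#' @export
mask_from_segments <- function(segments, n = attr(segments, "n")) {
  mask <- rep(FALSE, n)
  for (k in seq_len(nrow(segments)))
    mask[segments[k, "start"]:segments[k, "end"]] <- TRUE
  mask
}

#' Residue indices covered by a segment set
#' @param segments a `segment_set`.
#' @return Sorted integer vector of member residue indices.
#' @export
segment_residues <- function(segments) {
  if (!nrow(segments)) return(integer(0))
  unlist(lapply(seq_len(nrow(segments)),
                function(k) segments[k, "start"]:segments[k, "end"]))
}

#' Classify a protein as ID or noID
#'
#' A protein with at least one refined IDR is an "ID" protein; otherwise
#' "noID". Combined with a phase-separation label this yields the ID-PSP /
#' noID-PSP split.
#'
#' @param idrs a `segment_set` of refined IDRs.
#' @return `"ID"` or `"noID"`.
#' @export
classify_protein <- function(idrs) {
  if (nrow(idrs) > 0) "ID" else "noID"
}

#' Full IDR pipeline for one protein
#'
#' pLDDT thresholding, helix/sheet filtering, and refinement in one call.
#'
#' @param model a `protein_model`.
#' @param ss an `ss_assignment` (computed if missing).
#' @param config a [run_config()].
#' @return A `segment_set` of IDR intervals.
#' @export
find_idrs <- function(model, ss = NULL, config = run_config()) {
  if (is.null(ss)) ss <- assign_ss(model, backend = config$ss_backend)
  mask <- raw_disorder_mask(model$plddt, config$plddt_cutoff)
  mask <- filter_secondary_structure(mask, ss$states3)
  refine_mask(mask, smooth_order = config$smooth_order)
}

#' Export IDR intervals as BED text
#'
#' Internally intervals are 1-based inclusive; BED output is 0-based
#' half-open.
#'
#' @param segments a `segment_set`.
#' @param id protein/chromosome-style identifier for column 1.
#' @return Character vector of BED lines.
#' @export
idr_bed <- function(segments, id) {
  if (!nrow(segments)) return(character(0))
  sprintf("%s\t%d\t%d", id, segments[, "start"] - 1L, segments[, "end"])
}
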