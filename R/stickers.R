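## stickers: charged-sticker detection on the SSUP — net charge index,
## candidate screening, centroid-linkage clustering, summary features,
## and the distance-threshold scan.

#' Charge assignment
#'
#' Which residues count as positive / negative for the net charge index.
#' Histidine is excluded by default (pH-7 electrostatics).
#'
#' @param positive,negative character vectors of one-letter codes.
#' @return List with `positive` and `negative` components.
#' @export
charge_assignment <- function(positive = c("K", "R"),
                              negative = c("D", "E")) {
  if (length(intersect(positive, negative)))
    stop("positive and negative sets overlap")
  list(positive = positive, negative = negative)
}

#' Net charge index of SSUP residues
#'
#' For each SSUP residue i, NCI(i) is the number of positive SSUP
#' residues minus the number of negative SSUP residues within `distance`
#' of i (inclusive). A charged residue counts toward its own NCI
#' (distance zero). Distances are C-alpha--C-alpha by default; the
#' `"any"` metric uses the minimum heavy-atom pair distance.
#'
#' @param model a `protein_model`.
#' @param ssup integer vector of SSUP residue indices.
#' @param distance neighbour cutoff in angstrom (14).
#' @param charges a [charge_assignment()].
#' @param metric `"ca"` (default) or `"any"`.
#' @return Named integer vector, one entry per SSUP residue (names are
#'   residue indices). Empty when SSUP is empty.
#' @export
net_charge_index <- function(model, ssup, distance = 14,
                             charges = charge_assignment(),
                             metric = c("ca", "any")) {
  metric <- match.arg(metric)
  stopifnot(distance > 0)
  if (!length(ssup)) return(setNames(integer(0), character(0)))
  aa <- strsplit(model$sequence, "")[[1]][ssup]
  sign_of <- integer(length(ssup))
  sign_of[aa %in% charges$positive] <- 1L
  sign_of[aa %in% charges$negative] <- -1L

  if (metric == "ca") {
    co <- model$ca[ssup, , drop = FALSE]
    within <- as.matrix(stats::dist(co)) <= distance
    diag(within) <- TRUE
  } else {
    within <- residue_contact_matrix(model, ssup, distance)
  }
  nci <- as.integer(within %*% sign_of)
  setNames(nci, ssup)
}

## any-heavy-atom residue contact matrix for the subset `ssup`
residue_contact_matrix <- function(model, ssup, distance) {
  k <- length(ssup)
  a <- model$atoms[model$atoms$residue %in% ssup, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rid <- match(a$residue, ssup)
  d2 <- as.matrix(stats::dist(xyz))^2
  within <- matrix(FALSE, k, k)
  lim <- distance^2
  for (i in seq_len(k)) {
    rows <- rid == i
    hit <- d2[rows, , drop = FALSE] <= lim
    within[i, ] <- tapply(apply(hit, 2, any), rid, any)
  }
  diag(within) <- TRUE
  within | t(within)
}

#' Sticker candidate residues
#'
#' Residues whose absolute net charge index is strictly greater than the
#' cutoff (default 3, i.e. |NCI| >= 4).
#'
#' @param nci named NCI vector from [net_charge_index()].
#' @param cutoff strict threshold on |NCI| (3).
#' @return Integer vector of residue indices.
#' @export
candidate_residues <- function(nci, cutoff = 3) {
  as.integer(names(nci)[abs(nci) > cutoff])
}

#' Cluster sticker candidates by centroid linkage
#'
#' Agglomerative clustering of candidate residues on Euclidean C-alpha
#' coordinates with centroid linkage: at each step the two clusters whose
#' centroids (size-weighted means of member coordinates) are closest are
#' merged, while that distance does not exceed `distance`. Each final
#' cluster's sign is the majority sign of its members' NCI; exact ties
#' fall back to the sign of the summed NCI, and zero-sum clusters are
#' discarded with a warning.
#'
#' @param candidates integer vector of candidate residue indices.
#' @param ca n x 3 matrix of C-alpha coordinates for the whole protein.
#' @param distance merge cutoff in angstrom (14), the same value used for
#'   the NCI neighbourhood.
#' @param nci named NCI vector covering the candidates.
#' @return List of clusters, each a list with `sign` (+1/-1), `members`
#'   (residue indices) and `centroid` (length-3 numeric).
#' @export
cluster_stickers <- function(candidates, ca, distance = 14, nci) {
  if (!length(candidates)) return(list())
  co <- ca[candidates, , drop = FALSE]
  members <- as.list(seq_along(candidates))
  cent <- lapply(seq_along(candidates), function(i) co[i, ])
  size <- rep(1L, length(candidates))
  repeat {
    k <- length(members)
    if (k == 1) break
    cm <- do.call(rbind, cent)
    dm <- as.matrix(stats::dist(cm))
    diag(dm) <- Inf
    m <- which.min(dm)
    i <- (m - 1) %% k + 1
    j <- (m - 1) %/% k + 1
    if (dm[i, j] > distance) break
    lo <- min(i, j); hi <- max(i, j)
    new_members <- c(members[[lo]], members[[hi]])
    new_cent <- (cent[[lo]] * size[lo] + cent[[hi]] * size[hi]) /
      (size[lo] + size[hi])
    members[[lo]] <- new_members
    cent[[lo]] <- new_cent
    size[lo] <- size[lo] + size[hi]
    members[[hi]] <- NULL
    cent[[hi]] <- NULL
    size <- size[-hi]
  }
  out <- list()
  for (k in seq_along(members)) {
    res <- candidates[members[[k]]]
    v <- nci[as.character(res)]
    npos <- sum(v > 0); nneg <- sum(v < 0)
    sgn <- if (npos > nneg) 1L else if (nneg > npos) -1L else sign(sum(v))
    if (sgn == 0) {
      warning("discarding zero-sum sticker cluster at residues ",
              paste(res, collapse = ","))
      next
    }
    out[[length(out) + 1]] <-
      list(sign = as.integer(sgn), members = sort(res),
           centroid = unname(cent[[k]]))
  }
  out
}

#' Summarise sticker clusters
#'
#' Counts, the pair count (minimum of positive and negative cluster
#' counts), and SSUP-normalised frequencies. With an empty SSUP all
#' values are 0 by convention: a structured protein always has defined
#' sticker features, and zero encodes "no stickers possible".
#'
#' @param clusters list from [cluster_stickers()].
#' @param ssup_size number of SSUP residues.
#' @return List with `n_pos`, `n_neg`, `n_total`, `n_pairs`,
#'   `freq_sticker`, `freq_pair`.
#' @export
summarize_stickers <- function(clusters, ssup_size) {
  stopifnot(ssup_size >= 0)
  signs <- vapply(clusters, `[[`, integer(1), "sign")
  n_pos <- sum(signs > 0)
  n_neg <- sum(signs < 0)
  n_total <- n_pos + n_neg
  n_pairs <- min(n_pos, n_neg)
  if (ssup_size > 0) {
    fs <- n_total / ssup_size
    fp <- n_pairs / ssup_size
  } else {
    fs <- 0; fp <- 0
  }
  list(n_pos = n_pos, n_neg = n_neg, n_total = n_total, n_pairs = n_pairs,
       freq_sticker = fs, freq_pair = fp)
}

#' End-to-end sticker profile for one protein
#'
#' @param model a `protein_model`.
#' @param ssup integer vector of SSUP residues.
#' @param config a [run_config()].
#' @return List with `nci`, `candidates`, `clusters`, `summary`.
#' @export
sticker_profile <- function(model, ssup, config = run_config()) {
  charges <- charge_assignment(config$positive_set, config$negative_set)
  nci <- net_charge_index(model, ssup, distance = config$distance_threshold,
                          charges = charges, metric = config$nci_metric)
  cand <- candidate_residues(nci, config$nci_cutoff)
  clusters <- cluster_stickers(cand, model$ca,
                               distance = config$distance_threshold,
                               nci = nci)
  list(nci = nci, candidates = cand, clusters = clusters,
       summary = summarize_stickers(clusters, length(ssup)))
}

#' Scan the sticker distance threshold
#'
#' Recomputes sticker counts for each candidate distance and returns the
#' distance maximising the fraction of proteins with at least
#' `min_stickers` stickers (ties broken toward the smaller distance).
#'
#' @param analyses list of per-protein analyses from [analyze_structure()],
#'   or a list of `protein_model` objects (analysed on the fly).
#' @param distances candidate cutoffs in angstrom (10:20).
#' @param min_stickers sticker count defining the scanned fraction (3).
#' @param config a [run_config()].
#' @return List with `chosen` (the selected distance) and `fractions`
#'   (named numeric vector, one entry per candidate distance).
#' @export
threshold_scan <- function(analyses, distances = 10:20, min_stickers = 3,
                           config = run_config()) {
  stopifnot(length(analyses) >= 1)
  analyses <- lapply(analyses, function(x) {
    if (inherits(x, "protein_model")) analyze_structure(x, config = config)
    else x
  })
  fractions <- sapply(distances, function(d) {
    cfg <- config
    cfg$distance_threshold <- d
    counts <- vapply(analyses, function(a) {
      sticker_profile(a$model, a$ssup, cfg)$summary$n_total
    }, numeric(1))
    mean(counts >= min_stickers)
  })
  names(fractions) <- distances
  list(chosen = distances[which.max(fractions)], fractions = fractions)
}
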