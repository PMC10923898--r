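# Independent oracles. These are deliberately written with different
# mechanics than the package implementations they check.

# --- IDR refinement: single-conversion run walker -------------------------
# Converts one run at a time and rescans, instead of batch run-table edits.
oracle_refine <- function(mask, smooth_max = 3, bridge_max = 10,
                          min_len = 20) {
  runs <- function(m) {
    r <- rle(m)
    cbind(start = cumsum(r$lengths) - r$lengths + 1,
          end = cumsum(r$lengths), val = r$values, len = r$lengths)
  }
  convert_first <- function(m, state, maxlen) {
    r <- runs(m)
    for (k in seq_len(nrow(r))) {
      if (k == 1 || k == nrow(r)) next  # terminus: one flank only
      if (r[k, "val"] == state && r[k, "len"] <= maxlen) {
        m[r[k, "start"]:r[k, "end"]] <- !state
        return(list(m = m, changed = TRUE))
      }
    }
    list(m = m, changed = FALSE)
  }
  repeat {
    changed <- FALSE
    repeat {  # all short disordered runs first
      st <- convert_first(mask, TRUE, smooth_max)
      mask <- st$m
      if (!st$changed) break
      changed <- TRUE
    }
    repeat {  # then all short ordered runs
      st <- convert_first(mask, FALSE, smooth_max)
      mask <- st$m
      if (!st$changed) break
      changed <- TRUE
    }
    if (!changed) break
  }
  # single bridging pass
  r <- runs(mask)
  if (nrow(r) >= 3) {
    for (k in 2:(nrow(r) - 1)) {
      if (r[k, "val"] == 0 && r[k, "len"] <= bridge_max &&
          r[k - 1, "val"] == 1 && r[k - 1, "len"] >= min_len &&
          r[k + 1, "val"] == 1 && r[k + 1, "len"] >= min_len)
        mask[r[k, "start"]:r[k, "end"]] <- TRUE
    }
  }
  r <- runs(mask)
  keep <- r[r[, "val"] == 1 & r[, "len"] >= min_len, , drop = FALSE]
  out <- unname(keep[, c("start", "end"), drop = FALSE])
  storage.mode(out) <- "integer"
  out
}

segments_to_matrix <- function(segs) {
  m <- unclass(segs)
  attr(m, "n") <- NULL
  unname(m[, c("start", "end"), drop = FALSE])
}

# --- centroid-linkage clustering: recompute-from-scratch merger -----------
oracle_centroid_clusters <- function(points, threshold) {
  stopifnot(is.matrix(points))
  cl <- lapply(seq_len(nrow(points)), identity)
  repeat {
    if (length(cl) < 2) break
    cents <- t(vapply(cl, function(ix)
      colMeans(points[ix, , drop = FALSE]), numeric(3)))
    D <- as.matrix(stats::dist(cents))
    diag(D) <- Inf
    idx <- arrayInd(which.min(D), dim(D))
    if (D[idx] > threshold) break
    i <- min(idx); j <- max(idx)
    cl[[i]] <- c(cl[[i]], cl[[j]])
    cl[[j]] <- NULL
  }
  cl
}

canonical_membership <- function(list_of_member_vectors) {
  out <- lapply(list_of_member_vectors, sort)
  out[order(vapply(out, min, numeric(1)))]
}

# --- AUROC as a rank statistic -------------------------------------------
oracle_auroc_mwu <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores, ties.method = "average")
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# --- Monte Carlo Shrake-Rupley for tiny atom sets -------------------------
oracle_sasa_mc <- function(xyz, radii, probe, nsamp = 20000, seed = 99) {
  set.seed(seed)
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    pts <- matrix(rnorm(3 * nsamp), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * R
    pts <- sweep(pts, 2, xyz[i, ], "+")
    occ <- rep(FALSE, nsamp)
    for (j in seq_len(n)[-i]) {
      Rj <- radii[j] + probe
      d2 <- rowSums(sweep(pts, 2, xyz[j, ], "-")^2)
      occ <- occ | d2 < Rj^2
    }
    out[i] <- 4 * pi * R^2 * mean(!occ)
  }
  out
}

# --- shared test articles -------------------------------------------------
# square of four lysines with side `side`: candidates appear only once the
# NCI radius reaches the diagonal (side * sqrt(2))
square_charge_protein <- function(centres, side = 9.9, aa = "K",
                                  id = "square") {
  rows <- list()
  seqs <- character(0)
  res <- 0L
  offs <- list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0),
               C = c(1.2, 0.8, 0), O = c(1.8, 1.8, 0.4))
  corners <- list(c(0, 0), c(side, 0), c(side, side), c(0, side))
  for (ce in centres) {
    for (co in corners) {
      res <- res + 1L
      ca <- c(ce[1] + co[1], ce[2] + co[2], 0)
      for (nm in names(offs)) {
        rows[[length(rows) + 1]] <- data.frame(
          residue = res, name = nm, element = substr(nm, 1, 1),
          x = ca[1] + offs[[nm]][1], y = ca[2] + offs[[nm]][2],
          z = ca[3] + offs[[nm]][3], stringsAsFactors = FALSE)
      }
      seqs <- c(seqs, aa)
    }
  }
  new_protein_model(id, paste(seqs, collapse = ""), do.call(rbind, rows),
                    rep(90, length(seqs)))
}

random_mask <- function(n, p = 0.5) runif(n) < p

# small deterministic PDB text for parser tests
tiny_pdb_text <- function() {
  c(paste0("ATOM      1  N   GLY A   1       0.000   0.000   0.000",
           "  1.00 90.00           N"),
    paste0("ATOM      2  CA  GLY A   1       1.458   0.000   0.000",
           "  1.00 90.00           C"),
    paste0("ATOM      3  C   GLY A   1       2.000   1.400   0.000",
           "  1.00 90.00           C"),
    paste0("ATOM      4  O   GLY A   1       1.500   2.400   0.500",
           "  1.00 90.00           O"),
    paste0("ATOM      5  N   ALA A   2       3.300   1.500   0.000",
           "  1.00 40.00           N"),
    paste0("ATOM      6  CA  ALA A   2       4.200   2.600   0.200",
           "  1.00 40.00           C"),
    paste0("ATOM      7  C   ALA A   2       5.600   2.000   0.300",
           "  1.00 40.00           C"),
    paste0("ATOM      8  O   ALA A   2       5.900   0.900   0.700",
           "  1.00 40.00           O"),
    paste0("ATOM      9  N   LYS A   3       6.500   2.800   0.000",
           "  1.00 90.00           N"),
    paste0("ATOM     10  CA  LYS A   3       7.900   2.500   0.100",
           "  1.00 90.00           C"),
    paste0("ATOM     11  C   LYS A   3       8.700   3.800   0.200",
           "  1.00 90.00           C"),
    paste0("ATOM     12  O   LYS A   3       8.200   4.900   0.100",
           "  1.00 90.00           O"),
    "END")
}
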