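## fixtures: synthetic test articles with analytically known ground truth.
## Structures are geometric constructions, not physical proteins: ideal
## backbone geometry built by internal-coordinate chaining (NeRF), with
## controllable pLDDT and controllable spatial placement of charges.

## place atom D given A-B-C, bond |CD|, angle BCD (deg), torsion ABCD (deg)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("collinear reference atoms")
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

GEOMETRY_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                          extended = c(phi = -135, psi = 135))

#' Build a synthetic structure from ideal-geometry segments
#'
#' Chains one or more segments of ideal helix (phi = -57, psi = -47),
#' extended strand (phi = -135, psi = 135) or self-avoiding random coil
#' geometry into a single backbone (N, CA, C, O atoms), with a chosen
#' per-residue pLDDT and sequence pattern per segment. Coil torsions are
#' drawn from the polyproline-II-like region (phi in \[-150, -60\], psi in
#' \[60, 180\]), which keeps the chain expanded and free of backbone
#' hydrogen bonds; placements clashing below 3.2 A between non-adjacent
#' C-alphas are re-drawn.
#'
#' @param segments list of specs, each
#'   `list(length =, geometry = "helix"|"extended"|"coil", plddt =, pattern =)`
#'   (`pattern` is an amino-acid string recycled along the segment;
#'   defaults "A" for helix, "V" for extended, "G" for coil).
#' @param id protein identifier.
#' @param seed RNG seed (coil geometry only); deterministic output.
#' @param max_tries clash-resolution attempts per coil residue.
#' @return A `protein_model`.
#' @export
make_structure <- function(segments, id = "fixture", seed = 1,
                           max_tries = 200) {
  stopifnot(length(segments) >= 1)
  defaults <- c(helix = "A", extended = "V", coil = "G")
  aa <- character(0)
  plddt <- numeric(0)
  geom <- character(0)
  for (sg in segments) {
    stopifnot(sg$length >= 1, sg$plddt >= 0, sg$plddt <= 100)
    g <- match.arg(sg$geometry, c("helix", "extended", "coil"))
    pat <- if (is.null(sg$pattern)) defaults[[g]] else sg$pattern
    pat <- strsplit(pat, "")[[1]]
    aa <- c(aa, rep_len(pat, sg$length))
    plddt <- c(plddt, rep(sg$plddt, sg$length))
    geom <- c(geom, rep(g, sg$length))
  }
  n <- length(aa)

  with_seed(seed, {
    torsion_of <- function(g) {
      if (g == "coil")
        c(phi = stats::runif(1, -150, -60), psi = stats::runif(1, 60, 180))
      else GEOMETRY_TORSIONS[[g]]
    }
    ## bond lengths / angles: standard peptide values
    N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(1.458, 0, 0)
    ang <- 111.2 * pi / 180
    C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
    for (i in 2:max(2, n)) {
      if (i > n) break
      tries <- 0
      repeat {
        tor_prev <- torsion_of(geom[i - 1])
        tor_cur <- torsion_of(geom[i])
        Ni <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, tor_prev[["psi"]])
        CAi <- nerf_place(CA[i - 1, ], C[i - 1, ], Ni, 1.458, 121.7, 180)
        Ci <- nerf_place(C[i - 1, ], Ni, CAi, 1.525, 111.2,
                         tor_cur[["phi"]])
        ok <- TRUE
        if (i > 2) {
          d <- sqrt(rowSums((CA[1:(i - 2), , drop = FALSE] -
                               matrix(CAi, i - 2, 3, byrow = TRUE))^2))
          ok <- all(d >= 3.2)
        }
        if (ok || geom[i] != "coil" && geom[i - 1] != "coil") break
        tries <- tries + 1
        if (tries > max_tries)
          stop("unresolvable clash while placing coil residue ", i)
      }
      if (!ok) stop("unresolvable clash while placing residue ", i)
      N[i, ] <- Ni; CA[i, ] <- CAi; C[i, ] <- Ci
      ## carbonyl O of residue i-1: anti to the next amide
      O[i - 1, ] <- nerf_place(Ni, CA[i - 1, ], C[i - 1, ], 1.231, 120.8, 180)
    }
    psi_last <- torsion_of(geom[n])[["psi"]]
    O[n, ] <- nerf_place(N[n, ], CA[n, ], C[n, ], 1.231, 120.8,
                         psi_last + 180)
    if (n == 1) O[1, ] <- C[1, ] + c(0.62, 1.06, 0)

    atoms <- data.frame(
      residue = rep(seq_len(n), each = 4),
      name = rep(c("N", "CA", "C", "O"), n),
      element = rep(c("N", "C", "C", "O"), n),
      x = as.vector(rbind(N[, 1], CA[, 1], C[, 1], O[, 1])),
      y = as.vector(rbind(N[, 2], CA[, 2], C[, 2], O[, 2])),
      z = as.vector(rbind(N[, 3], CA[, 3], C[, 3], O[, 3])),
      stringsAsFactors = FALSE)
    new_protein_model(id, paste(aa, collapse = ""), atoms, plddt)
  })
}

#' Build a charged-sticker toy structure
#'
#' Places `n_pos_clusters` blobs of lysines and `n_neg_clusters` blobs of
#' aspartates, each blob holding `residues_per_cluster` residues on a
#' jittered 4 A circle (intra-blob C-alpha distances of roughly 5-8 A,
#' well below the 14 A clustering cutoff, yet open enough that every
#' residue stays solvent exposed) and blob centres at least
#' `cluster_spacing` apart on a line. All residues carry pLDDT 90 (no IDR possible) and the
#' structure is sparse, so every residue is solvent exposed; the expected
#' sticker counts are exactly the blob counts.
#'
#' @param n_pos_clusters,n_neg_clusters number of positive / negative
#'   blobs.
#' @param residues_per_cluster residues per blob (>= 4 so each member
#'   reaches |NCI| > 3 with self-inclusion).
#' @param cluster_spacing centre-to-centre spacing in angstrom (>= 40).
#' @param id protein identifier.
#' @param seed RNG seed for the in-blob jitter.
#' @return A `protein_model`.
#' @export
make_sticker_toy <- function(n_pos_clusters, n_neg_clusters,
                             residues_per_cluster = 4,
                             cluster_spacing = 50, id = "sticker_toy",
                             seed = 1) {
  stopifnot(residues_per_cluster >= 4, cluster_spacing >= 40)
  k <- n_pos_clusters + n_neg_clusters
  if (k == 0) {
    # chargeless control: a short strand of glycines
    return(make_structure(list(list(length = 8, geometry = "extended",
                                    plddt = 90, pattern = "G")),
                          id = id, seed = seed))
  }
  with_seed(seed, {
    rows <- list()
    aa <- character(0)
    res <- 0L
    for (b in seq_len(k)) {
      charge_aa <- if (b <= n_pos_clusters) "K" else "D"
      centre <- c((b - 1) * cluster_spacing, 0, 0)
      for (r in seq_len(residues_per_cluster)) {
        res <- res + 1L
        ## members on a 4 A circle: pairwise CA distances ~4.7-8 A, far
        ## below the 14 A cut but open enough to keep everyone exposed
        th <- 2 * pi * (r - 1) / residues_per_cluster
        ca <- centre + c(4 * cos(th), 4 * sin(th), 0) +
          stats::runif(3, -0.3, 0.3)
        offs <- list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0),
                     C = c(1.2, 0.8, 0), O = c(1.8, 1.8, 0.4))
        for (nm in names(offs)) {
          rows[[length(rows) + 1]] <- data.frame(
            residue = res, name = nm,
            element = substr(nm, 1, 1),
            x = ca[1] + offs[[nm]][1], y = ca[2] + offs[[nm]][2],
            z = ca[3] + offs[[nm]][3], stringsAsFactors = FALSE)
        }
        aa <- c(aa, charge_aa)
      }
    }
    atoms <- do.call(rbind, rows)
    new_protein_model(id, paste(aa, collapse = ""), atoms,
                      rep(90, length(aa)))
  })
}

#' Generate a labelled feature table with planted class structure
#'
#' Emits a table matching the real [feature_schema()]. All features are
#' Gaussian with mean 0.5 and sd 0.1; positives get their means shifted
#' by `effect_size` standard deviations on a subset of SSUP features
#' (charge/hydrophobicity/sticker columns, mirroring where the real
#' signal lives). A `missing_idr_fraction` of rows in each class has all
#' IDR features set missing, emulating noID proteins; positive rows with
#' missing IDR features are labelled noID-PSP, the rest ID-PSP.
#'
#' @param n_pos,n_neg class sizes (>= 10).
#' @param effect_size mean shift in units of the feature sd.
#' @param missing_idr_fraction fraction of rows with missing IDR features.
#' @param seed RNG seed.
#' @param use_phos include the phosphosite column?
#' @param signal_features columns carrying the planted shift.
#' @return data.frame with `id`, `label`, and all feature columns.
#' @export
make_labeled_features <- function(n_pos, n_neg, effect_size = 2,
                                  missing_idr_fraction = 0.3, seed = 42,
                                  use_phos = FALSE,
                                  signal_features = c(
                                    "group_Charged_ssup", "sticker_ssup",
                                    "sticker_pair_ssup", "hydropathy_ssup",
                                    "group_Hydrophobic_ssup",
                                    "fraction_L_ssup", "pI_ssup",
                                    "mw_ssup")) {
  stopifnot(n_pos >= 10, n_neg >= 10)
  schema <- feature_schema(use_phos)
  stopifnot(all(signal_features %in% schema))
  n <- n_pos + n_neg
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * length(schema), 0.5, 0.1), n,
                dimnames = list(NULL, schema))
    shift <- effect_size * 0.1
    X[seq_len(n_pos), signal_features] <-
      X[seq_len(n_pos), signal_features] + shift
    idr_cols <- grepl("_idr$", schema) | schema %in%
      c("idr_length", "idr_percent")
    miss_pos <- sample(seq_len(n_pos), round(missing_idr_fraction * n_pos))
    miss_neg <- n_pos + sample(seq_len(n_neg),
                               round(missing_idr_fraction * n_neg))
    X[c(miss_pos, miss_neg), idr_cols] <- NA_real_
    label <- c(ifelse(seq_len(n_pos) %in% miss_pos, "noID-PSP", "ID-PSP"),
               rep("non-PSP", n_neg))
    data.frame(id = sprintf("fix%05d", seq_len(n)), label = label,
               as.data.frame(X), stringsAsFactors = FALSE)
  })
}
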