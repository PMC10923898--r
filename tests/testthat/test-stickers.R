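test_that("net charge index counts signed SSUP neighbours, self included", {
  # 4 lysines mutually within 14 A, nothing else charged
  toy <- make_sticker_toy(1, 0, 4, 50, seed = 1)
  ssup <- seq_len(toy$n)
  nci <- net_charge_index(toy, ssup)
  expect_equal(unname(nci), rep(4L, 4))
  expect_equal(names(nci), as.character(1:4))
  # restricting the SSUP restricts the neighbour pool
  expect_equal(unname(net_charge_index(toy, 1:2)), rep(2L, 2))
})

test_that("NCI cancellation and the uncharged case", {
  # hand-built: 3 K and 3 D all within 14 A
  offs <- list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0),
               O = c(1.8, 1.8, 0.4))
  rows <- list()
  for (r in 1:6) {
    ca <- c(3 * cos(r), 3 * sin(r), 0)
    for (nm in names(offs))
      rows[[length(rows) + 1]] <- data.frame(
        residue = r, name = nm, element = substr(nm, 1, 1),
        x = ca[1] + offs[[nm]][1], y = ca[2] + offs[[nm]][2],
        z = ca[3] + offs[[nm]][3], stringsAsFactors = FALSE)
  }
  m <- new_protein_model("mix", "KKKDDD", do.call(rbind, rows), rep(90, 6))
  expect_equal(unname(net_charge_index(m, 1:6)), rep(0L, 6))
  # no charged residues at all
  g <- make_structure(list(list(length = 12, geometry = "extended",
                                plddt = 90, pattern = "G")), id = "g")
  expect_equal(unname(net_charge_index(g, 1:12)), rep(0L, 12))
  # empty SSUP yields an empty result, not an error
  expect_length(net_charge_index(g, integer(0)), 0)
})

test_that("candidate screening is strict in |NCI| > 3", {
  nci <- setNames(c(4L, 3L, -5L, -3L, 0L), c(10, 20, 30, 40, 50))
  expect_equal(candidate_residues(nci), c(10L, 30L))
})

test_that("clustering separates distant groups and handles degenerate input", {
  toy <- make_sticker_toy(2, 0, 5, 50, seed = 4)
  ssup <- seq_len(toy$n)
  nci <- net_charge_index(toy, ssup)
  cand <- candidate_residues(nci)
  expect_length(cand, 10)
  cl <- cluster_stickers(cand, toy$ca, 14, nci)
  expect_length(cl, 2)
  expect_equal(canonical_membership(lapply(cl, `[[`, "members")),
               list(1:5, 6:10))
  expect_equal(vapply(cl, `[[`, integer(1), "sign"), c(1L, 1L))
  # single candidate -> singleton cluster with that residue's sign
  one <- cluster_stickers(cand[1], toy$ca, 14, nci)
  expect_length(one, 1)
  expect_equal(one[[1]]$members, cand[1])
  # empty candidate set -> empty list
  expect_length(cluster_stickers(integer(0), toy$ca, 14, nci), 0)
})

test_that("clustering equals the exhaustive centroid-linkage oracle", {
  set.seed(21)
  for (rep in 1:60) {
    k <- sample(2:12, 1)
    pts <- matrix(runif(3 * k, 0, 40), k, 3)
    cand <- seq_len(k) * 3L  # arbitrary residue indices
    ca <- matrix(NA_real_, max(cand), 3)
    ca[cand, ] <- pts
    nci <- setNames(sample(c(-6L, 5L), k, replace = TRUE), cand)
    got <- cluster_stickers(cand, ca, 14, nci)
    want <- oracle_centroid_clusters(pts, 14)
    expect_equal(canonical_membership(lapply(got, `[[`, "members")),
                 canonical_membership(lapply(want, function(ix) cand[ix])))
  }
})

test_that("cluster signs follow the member majority with sum tie-break", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  nci <- setNames(c(5L, 4L, -4L), 1:3)
  cl <- cluster_stickers(1:3, pts, 14, nci)
  expect_equal(cl[[1]]$sign, 1L)
  # 1 vs 1 tie resolved by summed NCI
  nci2 <- setNames(c(6L, -4L), 1:2)
  cl2 <- cluster_stickers(1:2, pts[1:2, ], 14, nci2)
  expect_equal(cl2[[1]]$sign, 1L)
  # exact zero-sum cluster discarded with a warning
  nci3 <- setNames(c(4L, -4L), 1:2)
  expect_warning(cl3 <- cluster_stickers(1:2, pts[1:2, ], 14, nci3),
                 "zero-sum")
  expect_length(cl3, 0)
})

test_that("sticker summary arithmetic and empty-SSUP convention", {
  mk <- function(signs) lapply(signs, function(s)
    list(sign = s, members = 1L, centroid = c(0, 0, 0)))
  s <- summarize_stickers(mk(c(1L, -1L)), 100)
  expect_equal(s[c("n_total", "n_pairs", "freq_sticker", "freq_pair")],
               list(n_total = 2L, n_pairs = 1L, freq_sticker = 0.02,
                    freq_pair = 0.01))
  expect_equal(summarize_stickers(mk(c(1L, 1L, 1L)), 50)$n_pairs, 0L)
  empty <- summarize_stickers(list(), 0)
  expect_equal(empty$freq_sticker, 0)
  expect_equal(empty$freq_pair, 0)
})

test_that("NCI antisymmetry: swapping charge sets negates NCI and swaps counts", {
  toy <- make_sticker_toy(2, 1, 4, 45, seed = 9)
  an <- analyze_structure(toy)
  swapped <- charge_assignment(positive = c("D", "E"),
                               negative = c("K", "R"))
  nci <- net_charge_index(toy, an$ssup)
  nci_sw <- net_charge_index(toy, an$ssup, charges = swapped)
  expect_equal(unname(nci_sw), -unname(nci))
  cl <- cluster_stickers(candidate_residues(nci), toy$ca, 14, nci)
  cl_sw <- cluster_stickers(candidate_residues(nci_sw), toy$ca, 14, nci_sw)
  s <- summarize_stickers(cl, length(an$ssup))
  s_sw <- summarize_stickers(cl_sw, length(an$ssup))
  expect_equal(s_sw$n_pos, s$n_neg)
  expect_equal(s_sw$n_neg, s$n_pos)
  expect_equal(s_sw$n_total, s$n_total)
  expect_equal(s_sw$n_pairs, s$n_pairs)
})

test_that("sticker counts are invariant under rigid-body motion", {
  toy <- make_sticker_toy(2, 2, 4, 42, seed = 13)
  base <- analyze_structure(toy)$stickers$summary
  set.seed(33)
  for (rep in 1:3) {
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    shift <- rnorm(3, 0, 30)
    moved <- toy
    xyz <- as.matrix(toy$atoms[, c("x", "y", "z")]) %*% rot
    moved$atoms$x <- xyz[, 1] + shift[1]
    moved$atoms$y <- xyz[, 2] + shift[2]
    moved$atoms$z <- xyz[, 3] + shift[3]
    moved$ca <- moved$ca %*% rot
    moved$ca <- sweep(moved$ca, 2, shift, "+")
    got <- analyze_structure(moved)$stickers$summary
    expect_equal(got$n_total, base$n_total)
    expect_equal(got$n_pairs, base$n_pairs)
  }
})

test_that("the any-atom neighbour metric agrees with CA on compact toys", {
  toy <- make_sticker_toy(1, 1, 4, 50, seed = 2)
  ssup <- seq_len(toy$n)
  expect_equal(net_charge_index(toy, ssup, metric = "any"),
               net_charge_index(toy, ssup, metric = "ca"))
})

test_that("threshold scan maximises the >= 3 sticker fraction with low tie-break", {
  # squares whose diagonal (13.93 A) first fits inside a 14 A radius:
  # candidates appear exactly at the 14 A scan point
  squares <- square_charge_protein(list(c(0, 0), c(60, 0), c(120, 0)),
                                   side = 9.85)
  an <- analyze_structure(squares)
  expect_equal(length(an$ssup), squares$n)
  scan <- threshold_scan(list(an), distances = 10:20)
  expect_equal(unname(scan$fractions[as.character(10:13)]), rep(0, 4))
  expect_equal(unname(scan$fractions[as.character(14:20)]), rep(1, 7))
  expect_equal(scan$chosen, 14)
  # chargeless cohort: all fractions zero, smallest distance wins the tie
  g <- make_structure(list(list(length = 12, geometry = "extended",
                                plddt = 90, pattern = "G")), id = "g")
  scan0 <- threshold_scan(list(analyze_structure(g)), distances = 10:20)
  expect_true(all(scan0$fractions == 0))
  expect_equal(scan0$chosen, 10)
})
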