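toy_model <- function(seq = "GAKLR") {
  make_structure(list(list(length = nchar(seq), geometry = "extended",
                           plddt = 90, pattern = seq)), id = "toy")
}

test_that("region_sequence indexes residues in order", {
  m <- toy_model("GAKLR")
  expect_equal(region_sequence(m, 1:5), "GAKLR")
  expect_equal(region_sequence(m, integer(0)), "")
  expect_equal(region_sequence(m, c(2, 5)), "AR")
  expect_equal(region_sequence(m, segment_set(2, 4, 5)), "AKL")
})

test_that("amino-acid fractions sum to one and handle empty regions", {
  f <- aa_fractions("LLLL")
  expect_equal(unname(f["fraction_L"]), 1)
  expect_equal(sum(f), 1)
  f2 <- aa_fractions("ILKV")
  expect_equal(unname(f2[c("fraction_I", "fraction_L", "fraction_K",
                           "fraction_V")]), rep(0.25, 4))
  expect_true(all(is.na(aa_fractions(""))))
  set.seed(3)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "R", "N", "D", "C", "E", "G", "K", "L", "V"),
                      sample(5:60, 1), replace = TRUE), collapse = "")
    expect_equal(sum(aa_fractions(s)), 1, tolerance = 1e-9)
  }
})

test_that("group proportions follow the fifteen fixed groups", {
  g <- group_fractions("ILKV")
  expect_equal(unname(g["group_Xle"]), 0.5)
  g2 <- group_fractions("DEDE")
  expect_equal(unname(g2["group_Charged"]), 1)
  expect_equal(unname(g2["group_Neg_charged"]), 1)
  expect_equal(unname(g2["group_Pos_charged"]), 0)
  # Aliphatic {V,I,L,M} is a subset of Hydrophobic {V,I,L,F,W,Y,M}
  set.seed(4)
  for (rep in 1:10) {
    s <- paste(sample(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]],
                      sample(5:50, 1), replace = TRUE), collapse = "")
    g <- group_fractions(s)
    expect_lte(g[["group_Aliphatic"]], g[["group_Hydrophobic"]])
  }
})

test_that("hydropathy is the normalised Kyte-Doolittle mean", {
  expect_equal(mean_hydropathy(strrep("I", 8)), 1)
  expect_equal(mean_hydropathy(strrep("R", 8)), 0)
  expect_equal(mean_hydropathy("IR"), 0.5)
  expect_true(is.na(mean_hydropathy("")))
})

test_that("polarity is a straight scale average", {
  expect_equal(mean_polarity("GGG"), 0)
  expect_equal(mean_polarity("RR"), 52.0)
  # linearity: a 1:1 mix averages the homopolymer values
  expect_equal(mean_polarity("KD"),
               (mean_polarity("K") + mean_polarity("D")) / 2)
  set.seed(6)
  s <- paste(sample(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]], 30,
                    replace = TRUE), collapse = "")
  tab <- c(A = 0.00, R = 52.00, N = 3.38, D = 49.70, C = 1.48, E = 49.90,
           Q = 3.53, G = 0.00, H = 51.60, I = 0.13, L = 0.13, K = 49.50,
           M = 1.43, F = 0.35, P = 1.58, S = 1.67, T = 1.66, W = 2.10,
           Y = 1.61, V = 0.13)
  expect_equal(mean_polarity(s), mean(tab[strsplit(s, "")[[1]]]))
})

test_that("isoelectric point brackets basic and acidic peptides", {
  pk <- isoelectric_point(strrep("K", 10))
  pd <- isoelectric_point(strrep("D", 10))
  expect_gt(pk, 9)
  expect_lt(pd, 4)
  expect_true(is.na(isoelectric_point("")))
  # defining property: net charge at the returned pI is ~0
  charge_at <- function(seq, ph) {
    counts <- table(factor(strsplit(seq, "")[[1]],
                           levels = strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]))
    pos <- 1 / (1 + 10^(ph - 9.094)) +
      counts[["K"]] / (1 + 10^(ph - 10.0)) +
      counts[["R"]] / (1 + 10^(ph - 12.0)) +
      counts[["H"]] / (1 + 10^(ph - 5.98))
    neg <- -1 / (1 + 10^(2.869 - ph)) -
      counts[["D"]] / (1 + 10^(4.05 - ph)) -
      counts[["E"]] / (1 + 10^(4.45 - ph)) -
      counts[["C"]] / (1 + 10^(9.0 - ph)) -
      counts[["Y"]] / (1 + 10^(10.0 - ph))
    pos + neg
  }
  for (s in c("KDEEKRH", "AAAA", "KKDD")) {
    expect_lt(abs(charge_at(s, isoelectric_point(s))), 1e-2)
  }
})

test_that("molecular weight telescopes and matches glycine", {
  expect_equal(molecular_weight("G"), 75.0672, tolerance = 1e-4)
  expect_equal(molecular_weight("AG"),
               molecular_weight("A") + molecular_weight("G") - 18.0153)
  expect_true(is.na(molecular_weight("")))
})

test_that("IDR extent sums interval coverage", {
  expect_true(all(is.na(idr_extent(segment_set(), 100))))
  expect_equal(idr_extent(segment_set(1, 20, 100), 100),
               c(idr_length = 20, idr_percent = 0.2))
  expect_equal(idr_extent(segment_set(c(1, 50), c(20, 69), 100), 100),
               c(idr_length = 40, idr_percent = 0.4))
})

test_that("phosphosite frequency deduplicates and warns on overflow sites", {
  tab <- data.frame(id = c("P1", "P1", "P1", "P2"),
                    position = c(5, 5, 10, 3))
  expect_equal(phos_frequency("P1", 100, tab), 0.02)
  expect_equal(phos_frequency("absent", 100, tab), 0)
  expect_equal(phos_frequency("P1", 100, NULL), 0)
  expect_warning(f <- phos_frequency("P1", 8, tab), "beyond sequence length")
  expect_equal(f, 2 / 8)
})

test_that("feature vector assembly enforces schema and missingness rules", {
  toy <- make_sticker_toy(1, 1, 4, 50, seed = 5)
  an <- analyze_structure(toy)
  expect_equal(an$protein_type, "noID")
  fv <- analysis_features(an)
  expect_equal(names(fv), feature_schema(FALSE))
  # noID protein: every IDR feature missing, SSUP features populated
  expect_true(all(is.na(fv[grepl("_idr$|^idr_", names(fv))])))
  expect_false(anyNA(fv[grepl("_ssup$", names(fv))]))
  expect_equal(unname(fv["sticker_ssup"]), 2 / length(an$ssup))

  hc <- make_structure(list(list(length = 60, geometry = "helix", plddt = 90),
                            list(length = 30, geometry = "coil", plddt = 40)),
                       id = "hc", seed = 2)
  an2 <- analyze_structure(hc)
  expect_equal(an2$protein_type, "ID")
  fv2 <- analysis_features(an2)
  expect_false(anyNA(fv2[c("idr_length", "idr_percent")]))
  # ignore_idr makes an ID protein look like a noID protein
  cfg <- run_config(ignore_idr = TRUE)
  fv3 <- analysis_features(an2, config = cfg)
  expect_true(all(is.na(fv3[grepl("_idr$|^idr_", names(fv3))])))
  expect_equal(fv3[grepl("_ssup$", names(fv3))],
               fv2[grepl("_ssup$", names(fv2))])
  # schema is stable across proteins and the phos flag appends one name
  expect_equal(names(fv2), names(fv))
  expect_equal(setdiff(feature_schema(TRUE), feature_schema(FALSE)),
               "phos_frequency")
  expect_length(feature_schema(TRUE), 83)
})

test_that("SSUP composition features use exactly the SSUP residues", {
  toy <- make_sticker_toy(2, 1, 4, 45, seed = 8)
  an <- analyze_structure(toy)
  fv <- analysis_features(an)
  seq_ssup <- region_sequence(an$model, an$ssup)
  expect_equal(unname(fv["fraction_K_ssup"]),
               unname(aa_fractions(seq_ssup)["fraction_K"]))
  expect_equal(unname(fv["mw_ssup"]), molecular_weight(seq_ssup))
})
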