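# small hyperparameters keep the test suite fast; the algorithmic
# contract (10 members, 2:1 negatives, weights, missing routing) is
# unchanged
fast_hp <- function(n_estimators = 40, max_depth = 3) {
  hp <- default_hyperparameters()
  hp$n_estimators <- n_estimators
  hp$max_depth <- max_depth
  hp
}

test_that("split_dataset stratifies 1:1, honours reservations, and is deterministic", {
  d <- data.frame(id = sprintf("p%02d", 1:40),
                  label = rep(c("ID-PSP", "noID-PSP", "non-PSP"),
                              c(10, 10, 20)))
  s1 <- split_dataset(d, seed = 42)
  expect_equal(sum(s1$split == "train" & s1$label == "ID-PSP"), 5)
  expect_equal(sum(s1$split == "test" & s1$label == "noID-PSP"), 5)
  expect_equal(sum(s1$split == "train" & s1$label == "non-PSP"), 10)
  s2 <- split_dataset(d, seed = 42)
  expect_identical(s1$split, s2$split)
  expect_false(identical(split_dataset(d, seed = 7)$split, s1$split))
  # reserved rows always land in train
  d$reserved <- d$label == "ID-PSP" & d$id %in% sprintf("p%02d", 1:4)
  s3 <- split_dataset(d, seed = 1)
  expect_true(all(s3$split[s3$reserved] == "train"))
  expect_error(split_dataset(data.frame(id = "a", label = "ID-PSP")),
               "fewer than 2")
})

test_that("min-max scaling matches the affine contract", {
  X <- cbind(a = c(0, 10), b = c(5, 5), c = c(1, NA))
  sc <- fit_scaler(X)
  Y <- apply_scaler(sc, cbind(a = c(5, 12), b = c(5, 7), c = c(NA, 1)))
  expect_equal(Y[, "a"], c(0.5, 1.2))   # outside train range: no clipping
  expect_equal(Y[, "b"], c(0, 0))       # constant column -> 0
  expect_equal(Y[, "c"], c(NA, 0))      # missing stays missing
})

test_that("inverse-frequency weights equalise class mass", {
  labels <- rep(c("ID-PSP", "noID-PSP", "non-PSP"), c(10, 5, 85))
  w <- class_weights(labels)
  expect_equal(w[1] / w[11], 0.5)  # weights proportional to 1/10 vs 1/5
  mass <- as.numeric(tapply(w, labels, sum))
  expect_equal(mass / mass[1], rep(1, 3))
  expect_equal(unique(class_weights(rep(c("a", "b", "c"), each = 10))),
               3)
})

test_that("negative subsets are 2x positives, deterministic, distinct by round", {
  pool <- sprintf("n%03d", 1:200)
  s0 <- sample_negatives(pool, 10, 0, seed = 42)
  expect_length(s0, 20)
  expect_false(anyDuplicated(s0) > 0)
  expect_identical(s0, sample_negatives(pool, 10, 0, seed = 42))
  draws <- lapply(0:9, function(r) sort(sample_negatives(pool, 10, r, 42)))
  expect_equal(length(unique(draws)), 10)
  expect_error(sample_negatives(pool[1:15], 10, 0), "smaller than 2 x")
})

test_that("the boosted-tree learner separates planted signal and routes missing values", {
  set.seed(1)
  n <- 300
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  y <- as.numeric(X[, "x1"] + X[, "x2"] > 0)
  fit <- gbt_fit(X, y, hp = fast_hp(60), seed = 1)
  p <- predict(fit, X)
  expect_gt(auroc(p, y), 0.95)
  expect_true(all(p >= 0 & p <= 1))
  # informative missingness: NA pattern itself carries the class
  X2 <- cbind(x = ifelse(y == 1, NA, rnorm(n)), z = rnorm(n))
  fit2 <- gbt_fit(X2, y, hp = fast_hp(30), seed = 2)
  expect_gt(auroc(predict(fit2, X2), y), 0.95)
  expect_error(gbt_fit(X, rep(1, n)), "single-class")
})

test_that("ensemble training is deterministic and scores average the members", {
  d <- make_labeled_features(30, 90, effect_size = 2, seed = 10)
  ens1 <- train_ensemble(d, fast_hp(), seed = 42)
  ens2 <- train_ensemble(d, fast_hp(), seed = 42)
  probe <- make_labeled_features(10, 10, effect_size = 2, seed = 11)
  expect_identical(predict_ensemble(ens1, probe),
                   predict_ensemble(ens2, probe))
  expect_length(ens1$members, 10)
  # mean-bounds property: ensemble score between member extremes
  Xs <- apply_scaler(ens1$scaler,
                     pspredict:::as_feature_matrix(probe, ens1$schema))
  member_p <- sapply(ens1$members, function(m) predict(m, Xs))
  sc <- predict_ensemble(ens1, probe)$score
  expect_true(all(sc >= apply(member_p, 1, min) - 1e-12))
  expect_true(all(sc <= apply(member_p, 1, max) + 1e-12))
  expect_equal(sc, rowMeans(member_p))
})

test_that("prediction rejects schema mismatches by name", {
  d <- make_labeled_features(20, 40, seed = 3)
  ens <- train_ensemble(d, fast_hp(10), seed = 1)
  bad <- d[, setdiff(names(d), "sticker_ssup")]
  expect_error(predict_ensemble(ens, bad), "sticker_ssup")
})

test_that("model archives round-trip through JSON", {
  d <- make_labeled_features(20, 40, effect_size = 2, seed = 6)
  ens <- train_ensemble(d, fast_hp(15), seed = 42)
  dir <- withr::local_tempdir()
  save_model(ens, dir)
  back <- load_model(dir)
  probe <- make_labeled_features(10, 10, seed = 12)
  expect_equal(predict_ensemble(back, probe), predict_ensemble(ens, probe))
  expect_equal(back$schema, ens$schema)
  expect_equal(back$hp$n_estimators, 15)
})

test_that("hyperparameter tuning returns the argmax of its own trials", {
  # negative pool must exceed 2x positives inside every 2/3-sized fold
  d <- make_labeled_features(30, 100, effect_size = 2.5, seed = 20)
  res <- tune_hyperparameters(d, n_trials = 3, seed = 1,
                              n_members = 3, n_folds = 3)
  expect_equal(res$best_score, max(res$trials$cv_auroc))
  expect_true(all(c("learning_rate", "reg_alpha") %in% names(res$best)))
  expect_equal(nrow(res$trials), 3)
  # single trial returns that configuration
  res1 <- tune_hyperparameters(d, n_trials = 1, seed = 2,
                               n_members = 2, n_folds = 3)
  expect_equal(res1$best_score, res1$trials$cv_auroc[1])
  # bounds respected
  sp <- default_search_space()
  for (nm in names(sp)) {
    expect_gte(res$best[[nm]], sp[[nm]]$lo)
    expect_lte(res$best[[nm]], sp[[nm]]$hi)
  }
})
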