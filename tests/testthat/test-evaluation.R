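test_that("ROC/PRC areas behave on separable and random scores", {
  s <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  rp <- roc_prc(s, l)
  expect_equal(rp$auroc, 1)
  expect_equal(rp$auprc, 1)
  expect_error(roc_prc(s, rep(TRUE, 5)), "both classes")
  # labels independent of scores: AUROC ~ 0.5 at n = 2000
  set.seed(9)
  s2 <- runif(2000)
  l2 <- runif(2000) < 0.3
  expect_lt(abs(auroc(s2, l2) - 0.5), 0.05)
})

test_that("trapezoidal AUROC equals the Mann-Whitney rank statistic with ties", {
  set.seed(14)
  for (rep in 1:300) {
    n <- sample(3:12, 1)
    s <- sample(c(0.1, 0.2, 0.3, 0.4), n, replace = TRUE)  # forced ties
    l <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(auroc(s, l), oracle_auroc_mwu(s, l), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(15)
  s <- rnorm(100)
  l <- c(TRUE, FALSE, runif(98) < 0.4)
  a <- auroc(s, l)
  expect_equal(auroc(exp(s), l), a)
  expect_equal(auroc(2 * s + 7, l), a)
  expect_equal(select_threshold(roc_prc(s, l)$roc) |> (\(t) {
    r <- roc_prc(s, l)$roc
    r[r$threshold == t, c("fpr", "tpr")]
  })(), {
    r2 <- roc_prc(exp(s), l)$roc
    t2 <- select_threshold(r2)
    r2[r2$threshold == t2, c("fpr", "tpr")]
  }, ignore_attr = TRUE)
})

test_that("threshold selection minimises distance to the top-left corner", {
  # hand-computable 4-point curve
  s <- c(0.9, 0.7, 0.4, 0.2)
  l <- c(TRUE, FALSE, TRUE, FALSE)
  roc <- roc_prc(s, l)$roc
  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  expect_equal(select_threshold(roc), roc$threshold[which.min(d)])
  # brute force over every threshold on random sets
  set.seed(16)
  for (rep in 1:20) {
    s <- round(runif(12), 2)
    l <- c(TRUE, FALSE, runif(10) < 0.5)
    roc <- roc_prc(s, l)$roc
    dd <- roc$fpr^2 + (1 - roc$tpr)^2
    expect_equal(min(dd),
                 with(roc[roc$threshold == select_threshold(roc), ],
                      fpr^2 + (1 - tpr)^2)[1])
  }
  # perfect classifier: chosen point has distance 0
  roc <- roc_prc(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE))$roc
  t <- select_threshold(roc)
  expect_equal(with(roc[roc$threshold == t, ], fpr^2 + (1 - tpr)^2), 0)
})

test_that("confusion-matrix metrics follow the standard formulas", {
  # TP=2, FP=1, TN=3, FN=0 at threshold 0.5
  s <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.2)
  l <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m <- binary_metrics(s, l, 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$fpr, 0.25)
  expect_equal(m$fnr, 0)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$f1, 2 * 2 / (2 * 2 + 1 + 0))
  expect_equal(m$mcc, (2 * 3 - 1 * 0) / sqrt(3 * 2 * 4 * 3))
  # all predicted positive
  m2 <- binary_metrics(s, l, 0)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  # label swap with score negation exchanges sensitivity and specificity
  m3 <- binary_metrics(-s, !l, -0.5 + 1e-9)
  expect_equal(m3$sensitivity, m$specificity)
  expect_equal(m3$specificity, m$sensitivity)
  # rate identities hold by construction
  expect_equal(m$fpr, 1 - m$specificity)
  expect_equal(m$fnr, 1 - m$sensitivity)
})

test_that("MCC degenerates to 0 when a marginal is empty", {
  s <- c(0.9, 0.8, 0.1)
  l <- c(TRUE, TRUE, FALSE)
  expect_equal(binary_metrics(s, l, 0.01)$mcc, 0)  # no predicted negatives
})

test_that("the MLO protocol excludes training positives and splits by IDR class", {
  scores <- setNames(c(0.9, 0.85, 0.8, 0.2, 0.3, 0.1, 0.15),
                     c("m1", "m2", "m3", "n1", "n2", "n3", "n4"))
  idr_class <- setNames(c("ID", "noID", "ID", NA, NA, NA, NA), names(scores))
  res <- mlo_protocol(c("m1", "m2", "m3"), character(0),
                      c("n1", "n2", "n3", "n4"), scores, idr_class)
  expect_equal(res$ID$n_pos, 2)
  expect_equal(res$noID$n_pos, 1)
  expect_gt(res$ID$auroc, 0.9)
  # MLO set entirely inside the training positives: both classes undefined
  res2 <- mlo_protocol(c("m1", "m2"), c("m1", "m2"),
                       c("n1", "n2"), scores, idr_class)
  expect_null(res2$ID)
  expect_null(res2$noID)
  # disjoint training set leaves positives untouched
  res3 <- mlo_protocol(c("m1", "m2", "m3"), c("other"),
                       c("n1", "n2", "n3", "n4"), scores, idr_class)
  expect_equal(res3$ID$n_pos, res$ID$n_pos)
})
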