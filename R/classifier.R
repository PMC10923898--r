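## classifier: dataset split, min-max scaling, inverse-frequency weights,
## negative-subsample ensemble of gradient-boosted trees, random-search
## hyperparameter tuning, and prediction.

PSP_LABELS <- c("ID-PSP", "noID-PSP", "non-PSP")

## evaluate `code` under a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit a single gradient-boosted tree model
#'
#' Binary logistic gradient boosting with second-order splits, L1/L2 leaf
#' regularisation, minimum-gain pruning, row/column subsampling, and
#' native missing-value routing (each split learns a default direction
#' for NA). Missing features are therefore consumed as-is, never imputed.
#'
#' @param X numeric matrix (rows = samples); NA allowed.
#' @param y 0/1 response.
#' @param w per-row sample weights (default 1).
#' @param hp hyperparameter list, see [default_hyperparameters()].
#' @param seed integer seed for the row/column subsampling streams.
#' @return Object of class `gbt_model`.
#' @export
gbt_fit <- function(X, y, w = rep(1, length(y)), hp = default_hyperparameters(),
                    seed = 42) {
  stopifnot(is.matrix(X), nrow(X) == length(y), length(w) == length(y),
            all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("single-class training set")
  trees <- .gbt_train_cpp(X, as.numeric(y), as.numeric(w),
                          as.integer(hp$n_estimators), hp$learning_rate,
                          as.integer(hp$max_depth), hp$min_child_weight,
                          hp$subsample, hp$colsample_bytree, hp$gamma,
                          hp$reg_lambda, hp$reg_alpha, as.integer(seed))
  structure(list(trees = trees, p = ncol(X), hp = hp, seed = seed),
            class = "gbt_model")
}

#' Predict probabilities from a gradient-boosted tree model
#' @param object a `gbt_model`.
#' @param X numeric matrix with the training column count.
#' @param ... unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.gbt_model <- function(object, X, ...) {
  stopifnot(is.matrix(X), ncol(X) == object$p)
  as.numeric(.gbt_predict_cpp(object$trees, X))
}

#' Default hyperparameters (desk scale)
#' @return Named list of the nine tunable hyperparameters.
#' @export
default_hyperparameters <- function() {
  list(learning_rate = 0.1, n_estimators = 100, max_depth = 4,
       min_child_weight = 1, subsample = 0.8, colsample_bytree = 0.8,
       gamma = 0, reg_lambda = 1, reg_alpha = 0)
}

#' Hyperparameter search space
#'
#' Conventional wide bounds for the nine tuned hyperparameters (the
#' published search ranges are not available in the main text).
#'
#' @return List of `c(lo, hi)` bounds; `log = TRUE` entries are sampled
#'   log-uniformly, integer entries uniformly on the integer range.
#' @export
default_search_space <- function() {
  list(learning_rate = list(lo = 0.01, hi = 0.3, log = TRUE),
       n_estimators = list(lo = 50, hi = 300, int = TRUE),
       max_depth = list(lo = 2, hi = 8, int = TRUE),
       min_child_weight = list(lo = 1, hi = 10),
       subsample = list(lo = 0.5, hi = 1),
       colsample_bytree = list(lo = 0.5, hi = 1),
       gamma = list(lo = 0, hi = 5),
       reg_lambda = list(lo = 0.1, hi = 10, log = TRUE),
       reg_alpha = list(lo = 1e-3, hi = 1, log = TRUE))
}

sample_hyperparameters <- function(space = default_search_space()) {
  out <- lapply(space, function(s) {
    if (isTRUE(s$log)) v <- exp(stats::runif(1, log(s$lo), log(s$hi)))
    else v <- stats::runif(1, s$lo, s$hi)
    if (isTRUE(s$int)) v <- as.integer(round(v))
    v
  })
  out
}

#' Split a labelled dataset into training and testing halves
#'
#' ID-PSPs, noID-PSPs and non-PSPs are each split 1:1 (training share =
#' ceiling of half), stratified, deterministic under `seed`. Rows flagged
#' `reserved` are forced into the training half before the random draw.
#'
#' @param data data.frame with columns `id`, `label` (one of ID-PSP,
#'   noID-PSP, non-PSP) and optionally logical `reserved`.
#' @param seed RNG seed (42).
#' @return The input with an added `split` column (`"train"`/`"test"`).
#' @export
split_dataset <- function(data, seed = 42) {
  stopifnot(all(c("id", "label") %in% names(data)),
            all(data$label %in% PSP_LABELS), !anyDuplicated(data$id))
  if (is.null(data$reserved)) data$reserved <- FALSE
  data$split <- NA_character_
  with_seed(seed, {
    for (lb in unique(data$label)) {
      idx <- which(data$label == lb)
      if (length(idx) < 2) stop("fewer than 2 rows in stratum ", lb)
      n_train <- ceiling(length(idx) / 2)
      forced <- idx[data$reserved[idx]]
      rest <- setdiff(idx, forced)
      extra <- max(0, n_train - length(forced))
      pick <- if (extra > 0) sample(rest, min(extra, length(rest))) else integer(0)
      tr <- union(forced, pick)
      data$split[tr] <- "train"
      data$split[setdiff(idx, tr)] <- "test"
    }
  })
  data
}

#' Fit a min-max scaler on training rows
#'
#' @param X numeric matrix of training rows (NA ignored per column).
#' @return Object of class `scaler_params`: per-feature min and max.
#' @export
fit_scaler <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 1)
  mn <- apply(X, 2, function(v) if (all(is.na(v))) 0 else min(v, na.rm = TRUE))
  mx <- apply(X, 2, function(v) if (all(is.na(v))) 0 else max(v, na.rm = TRUE))
  structure(list(min = mn, max = mx), class = "scaler_params")
}

#' Apply a min-max scaler
#'
#' x' = (x - min) / (max - min); missing stays missing; constant columns
#' map to 0; test values outside the training range are not clipped.
#'
#' @param params a `scaler_params`.
#' @param X numeric matrix.
#' @return Scaled matrix.
#' @export
apply_scaler <- function(params, X) {
  stopifnot(ncol(X) == length(params$min))
  rng <- params$max - params$min
  out <- sweep(X, 2, params$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- ifelse(is.na(out[, rng == 0]), NA, 0)
  out
}

#' Inverse-frequency sample weights
#'
#' Each row is weighted by N_total / count(its class), so every class
#' carries the same total weighted mass.
#'
#' @param labels character vector of 3-class labels.
#' @return Numeric weight per row.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0)) stop("empty class")
  unname(length(labels) / as.numeric(tab[labels]))
}

#' Draw one negative training subset
#'
#' Uniform sample without replacement of `2 * n_positives` negatives;
#' deterministic under `(seed, round_index)`.
#'
#' @param negative_pool vector of negative identifiers (or indices).
#' @param n_positives positive count the subset is sized against.
#' @param round_index ensemble member index (0-based).
#' @param seed base seed.
#' @return Subset of `negative_pool`.
#' @export
sample_negatives <- function(negative_pool, n_positives, round_index, seed = 42) {
  n_draw <- 2 * n_positives
  if (length(negative_pool) < n_draw)
    stop("negative pool (", length(negative_pool),
         ") smaller than 2 x positives (", n_draw, ")")
  with_seed(seed * 1000L + round_index, sample(negative_pool, n_draw))
}

as_feature_matrix <- function(data, schema) {
  missing <- setdiff(schema, names(data))
  extra <- setdiff(names(data), c(schema, "id", "label", "split",
                                  "protein_type", "n_ssup", "n_stickers",
                                  "reserved"))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  m <- as.matrix(data[, schema, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Train the negative-subsample ensemble
#'
#' Fits one min-max scaler on the full training rows, then ten boosted
#' tree models, each on all positives plus a distinct negative subset of
#' twice the positive count, with inverse-frequency 3-class sample
#' weights. The ensemble score is the mean of the ten member
#' probabilities.
#'
#' @param train data.frame with `id`, `label` and the feature columns of
#'   [feature_schema()].
#' @param hp hyperparameters, see [default_hyperparameters()].
#' @param seed base seed (42).
#' @param use_phos whether the schema includes `phos_frequency`.
#' @param n_members ensemble size (10).
#' @return Object of class `ensemble_model`.
#' @export
train_ensemble <- function(train, hp = default_hyperparameters(), seed = 42,
                           use_phos = FALSE, n_members = 10) {
  schema <- feature_schema(use_phos)
  X <- as_feature_matrix(train, schema)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  pos <- which(train$label != "non-PSP")
  neg <- which(train$label == "non-PSP")
  if (!length(pos) || !length(neg)) stop("training set needs both classes")
  members <- vector("list", n_members)
  for (r in seq_len(n_members) - 1L) {
    sub <- c(pos, sample_negatives(neg, length(pos), r, seed))
    y <- as.numeric(train$label[sub] != "non-PSP")
    w <- class_weights(train$label[sub])
    members[[r + 1L]] <- gbt_fit(Xs[sub, , drop = FALSE], y, w, hp,
                                 seed = seed * 100L + r)
  }
  structure(list(members = members, scaler = scaler, hp = hp,
                 schema = schema, use_phos = use_phos, seed = seed),
            class = "ensemble_model")
}

#' Score proteins with a trained ensemble
#'
#' @param model an `ensemble_model`.
#' @param data data.frame (or named matrix) holding the model's feature
#'   schema; extra metadata columns are ignored.
#' @return data.frame with `score` (mean of member probabilities, in
#'   \[0, 1\]) and `score_sd` (member spread); row order preserved.
#' @export
predict_ensemble <- function(model, data) {
  if (is.matrix(data)) data <- as.data.frame(data)
  X <- as_feature_matrix(data, model$schema)
  Xs <- apply_scaler(model$scaler, X)
  probs <- sapply(model$members, function(m) predict(m, Xs))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  data.frame(score = rowMeans(probs), score_sd = apply(probs, 1, stats::sd))
}

#' Tune hyperparameters by cross-validated random search
#'
#' Stratified 5-fold cross-validation on the training set. In each fold
#' the positive training/validation and negative validation subsets stay
#' fixed while ten negative training subsets (2:1) are drawn; the fold
#' score is the AUROC of the averaged member score for ID-PSP vs non-PSP
#' validation rows. Configurations are sampled uniformly (log-uniformly
#' where conventional) from `space`; the best mean-AUROC configuration is
#' returned.
#'
#' @param train training data.frame (`id`, `label`, features).
#' @param n_trials number of sampled configurations (desk scale 50;
#'   the full published protocol used 1000).
#' @param seed base seed (42).
#' @param space search bounds, see [default_search_space()].
#' @param use_phos schema flag.
#' @param n_members ensemble size per fold (10).
#' @param n_folds folds (5).
#' @param scale_mode `"fold"` fits the min-max scaler inside each fold
#'   (no leakage, default); `"full"` fits once on the whole training set.
#' @return List: `best` (hyperparameters), `best_score`, and `trials`
#'   (data.frame of all evaluated configurations and scores).
#' @export
tune_hyperparameters <- function(train, n_trials = 50, seed = 42,
                                 space = default_search_space(),
                                 use_phos = FALSE, n_members = 10,
                                 n_folds = 5,
                                 scale_mode = c("fold", "full")) {
  scale_mode <- match.arg(scale_mode)
  if (!any(train$label == "ID-PSP")) stop("no ID-PSPs in training data")
  folds <- with_seed(seed, {
    f <- integer(nrow(train))
    for (lb in unique(train$label)) {
      idx <- sample(which(train$label == lb))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  if (any(vapply(seq_len(n_folds),
                 function(k) sum(train$label == "ID-PSP" & folds == k) == 0,
                 logical(1))))
    stop("a fold lacks ID-PSPs; too few positives for ", n_folds, " folds")
  schema <- feature_schema(use_phos)
  full_scaler <- if (scale_mode == "full")
    fit_scaler(as_feature_matrix(train, schema))

  trials <- vector("list", n_trials)
  scores <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    hp <- with_seed(seed + 7717L * t, sample_hyperparameters(space))
    fold_auc <- numeric(n_folds)
    for (k in seq_len(n_folds)) {
      tr <- train[folds != k, , drop = FALSE]
      va <- train[folds == k, , drop = FALSE]
      ens <- train_ensemble(tr, hp, seed = seed + k, use_phos = use_phos,
                            n_members = n_members)
      if (scale_mode == "full") ens$scaler <- full_scaler
      sc <- predict_ensemble(ens, va)$score
      keep <- va$label %in% c("ID-PSP", "non-PSP")
      fold_auc[k] <- auroc(sc[keep], va$label[keep] == "ID-PSP")
    }
    trials[[t]] <- hp
    scores[t] <- mean(fold_auc)
  }
  best <- which.max(scores)
  tr_df <- cbind(do.call(rbind, lapply(trials, as.data.frame)),
                 cv_auroc = scores)
  list(best = trials[[best]], best_score = scores[best], trials = tr_df)
}

#' Save / load an ensemble model archive
#'
#' The archive is a directory of JSON files: metadata (schema, scaler,
#' hyperparameters, seed, flags) plus one file per boosted-tree member.
#'
#' @param model an `ensemble_model`.
#' @param dir archive directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema = model$schema, use_phos = model$use_phos,
               seed = model$seed, hp = model$hp,
               scaler = list(min = as.numeric(model$scaler$min),
                             max = as.numeric(model$scaler$max)),
               n_members = length(model$members))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(model$members)) {
    m <- model$members[[i]]
    jsonlite::write_json(list(p = m$p, seed = m$seed, trees = m$trees),
                         file.path(dir, sprintf("member_%02d.json", i)),
                         digits = NA)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  members <- lapply(seq_len(meta$n_members), function(i) {
    raw <- jsonlite::read_json(file.path(dir, sprintf("member_%02d.json", i)),
                               simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
    trees <- lapply(raw$trees, function(tr) {
      list(feat = as.integer(tr$feat), thr = as.numeric(tr$thr),
           left = as.integer(tr$left), right = as.integer(tr$right),
           defleft = as.integer(tr$defleft), value = as.numeric(tr$value))
    })
    structure(list(trees = trees, p = as.integer(raw$p[[1]]), hp = meta$hp,
                   seed = raw$seed[[1]]),
              class = "gbt_model")
  })
  structure(list(members = members,
                 scaler = structure(list(min = stats::setNames(
                   meta$scaler$min, meta$schema),
                   max = stats::setNames(meta$scaler$max, meta$schema)),
                   class = "scaler_params"),
                 hp = meta$hp, schema = meta$schema,
                 use_phos = meta$use_phos, seed = meta$seed),
            class = "ensemble_model")
}
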