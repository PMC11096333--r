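#' Decoding configuration
#'
#' Per-time-point four-class decoding of omitted-note identity from the 34
#' channel voltages with repeated stratified k-fold cross-validation.
#' Defaults pin the paper-faithful scheme: threefold cross-validation
#' repeated 20 times over the full -200..300 ms range, One-vs-Rest
#' linear-margin classifiers on raw microvolts. `block_averaging` follows the
#' participant-based ERP decoding approach in which the trials of each
#' class x block are averaged into a single observation before
#' classification; a single-trial mode is available for comparison.
#' `decimation_ms` evaluates every k-th millisecond for desk-scale runs
#' (1 = every sample, paper-faithful).
#'
#' @param n_folds folds (default 3).
#' @param n_iterations re-partitioning iterations (default 20).
#' @param cost regularization constant of the linear SVM (default 1).
#' @param scaling `"none"` (default, raw uV) or `"train"` (standardize with
#'   training-fold statistics).
#' @param block_averaging average trials within class x fold before
#'   classification (default TRUE).
#' @param decode_range ms pair (default -200..300).
#' @param equalize_classes subsample every class to the smallest class count
#'   rounded down to a multiple of `n_folds` (default TRUE).
#' @param decimation_ms time step between decoded samples, ms.
#' @param seed RNG seed for partitioning/subsampling.
#' @return list of class `decode_config`.
#' @export
decode_config <- function(n_folds = 3, n_iterations = 20, cost = 1,
                          scaling = c("none", "train"),
                          block_averaging = TRUE,
                          decode_range = c(-200, 300),
                          equalize_classes = TRUE,
                          decimation_ms = 1, seed = 1L) {
  scaling <- match.arg(scaling)
  stopifnot(n_folds >= 2, n_iterations >= 1, cost > 0, decimation_ms >= 1)
  structure(list(n_folds = n_folds, n_iterations = n_iterations, cost = cost,
                 scaling = scaling, block_averaging = block_averaging,
                 decode_range = decode_range,
                 equalize_classes = equalize_classes,
                 decimation_ms = decimation_ms, seed = as.integer(seed)),
            class = "decode_config")
}

note_levels <- function() c("E", "F", "A", "C")

#' Stratified fold assignment
#'
#' Randomly splits each class's epochs as evenly as possible across folds.
#' With `equalize`, classes are first subsampled to the minimum class count
#' rounded down to a multiple of `n_folds` (subsampled-out epochs get fold
#' `NA`). Deterministic given the R RNG state.
#'
#' @param labels note label per epoch.
#' @param n_folds number of folds.
#' @param equalize equalize class counts first.
#' @return integer fold id per epoch (`NA` = not used this iteration).
#' @export
partition_classes <- function(labels, n_folds = 3, equalize = TRUE) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("class with fewer epochs than folds: ",
         paste(names(counts)[counts < n_folds], collapse = ", "),
         " (participant should have been excluded upstream)")
  fold <- rep(NA_integer_, length(labels))
  m <- if (equalize) n_folds * (min(counts) %/% n_folds) else NA
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    if (equalize) idx <- sample(idx, m)
    k <- length(idx)
    f <- rep_len(seq_len(n_folds), k)               # as even as possible
    fold[idx] <- sample(f)                          # random assignment
  }
  fold
}

#' Decode one time point
#'
#' Trains One-vs-Rest linear-margin classifiers on the training observations
#' and returns the fraction of test observations classified correctly. Ties
#' between decision values go to the earliest class in E, F, A, C order.
#'
#' @param train_features,test_features observations x channels matrices (uV).
#' @param train_labels,test_labels note labels.
#' @param config a [decode_config()].
#' @return accuracy fraction.
#' @export
decode_timepoint <- function(train_features, train_labels,
                             test_features, test_labels,
                             config = decode_config()) {
  lev_all <- unique(as.character(train_labels))
  lev <- if (all(lev_all %in% note_levels()))
    intersect(note_levels(), lev_all) else sort(lev_all)
  if (length(lev) < 2) stop("degenerate single-class training set")
  ytr <- match(as.character(train_labels), lev)
  yte <- match(as.character(test_labels), lev)
  Xtr <- as.matrix(train_features)
  Xte <- as.matrix(test_features)
  if (config$scaling == "train") {
    mu <- colMeans(Xtr); s <- apply(Xtr, 2, sd); s[s == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, s, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, s, "/")
  }
  pred <- ovr_svm_predict_cpp(Xtr, ytr, Xte, length(lev), config$cost)
  mean(!is.na(yte) & pred == yte)   # labels unseen in training count as misses
}

build_observations <- function(X, labels, fold, config) {
  lev <- note_levels()
  d <- dim(X)
  if (config$block_averaging) {
    combos <- expand.grid(class = seq_along(lev), fold = seq_len(config$n_folds))
    keep <- logical(nrow(combos))
    obs <- array(0, dim = c(d[1], d[2], nrow(combos)))
    for (i in seq_len(nrow(combos))) {
      idx <- which(labels == lev[combos$class[i]] &
                   !is.na(fold) & fold == combos$fold[i])
      if (length(idx) == 0) next
      keep[i] <- TRUE
      obs[, , i] <- if (length(idx) == 1) X[, , idx] else
        array(rowMeans(matrix(X[, , idx], nrow = d[1] * d[2])), dim = d[1:2])
    }
    list(obs = obs[, , keep, drop = FALSE],
         cls = combos$class[keep], fold = combos$fold[keep])
  } else {
    idx <- which(!is.na(fold))
    list(obs = X[, , idx, drop = FALSE],
         cls = match(labels[idx], lev), fold = fold[idx])
  }
}

#' Time-resolved decoding accuracy
#'
#' For every decoded time point and iteration: re-partition the retained
#' epochs into stratified folds, optionally average trials within each
#' class x fold into one observation, rotate folds so each is tested once,
#' and average accuracies over folds; iteration means are then averaged.
#'
#' @param epochs a preprocessed `epoch_set` (retained flags honoured).
#' @param config a [decode_config()].
#' @return list of class `accuracy_series`: `time` (ms), `accuracy`,
#'   `participant_id`, `condition`, `n_classes`, `chance`.
#' @export
decode_timecourse <- function(epochs, config = decode_config()) {
  sel <- which(epochs$retained)
  labels <- epochs$labels[sel]
  t_keep <- epochs$time >= config$decode_range[1] - 1e-9 &
            epochs$time <= config$decode_range[2] + 1e-9
  if (!any(t_keep)) stop("decode range outside epoch span")
  X <- epochs$data[t_keep, , sel, drop = FALSE]
  time <- epochs$time[t_keep]
  step <- 1000 / epochs$fs
  tidx <- seq(1, length(time), by = max(1L, round(config$decimation_ms / step)))
  set.seed(config$seed)
  acc <- numeric(length(tidx))
  for (it in seq_len(config$n_iterations)) {
    fold <- partition_classes(labels, config$n_folds, config$equalize_classes)
    ob <- build_observations(X, labels, fold, config)
    a <- decode_timepoints_cpp(ob$obs, ob$cls, ob$fold, tidx,
                               n_class = length(note_levels()),
                               n_folds = config$n_folds, cost = config$cost,
                               standardize = config$scaling == "train")
    acc <- acc + rowMeans(a)
  }
  structure(list(time = time[tidx], accuracy = acc / config$n_iterations,
                 participant_id = epochs$participant_id,
                 condition = epochs$condition,
                 n_classes = 4L, chance = 0.25),
            class = "accuracy_series")
}

#' Mean accuracy over a time window
#'
#' @param series an `accuracy_series`.
#' @param window ms pair, inclusive endpoints.
#' @return mean accuracy fraction.
#' @export
window_mean_accuracy <- function(series, window) {
  sel <- series$time >= window[1] - 1e-9 & series$time <= window[2] + 1e-9
  if (!any(sel)) stop("window contains no decoded time points")
  mean(series$accuracy[sel])
}
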