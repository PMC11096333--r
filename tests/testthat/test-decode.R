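test_that("partitioning is stratified, equalized and deterministic", {
  labels <- rep(c("E", "F", "A", "C"), times = c(60, 60, 60, 70))
  set.seed(10)
  fold <- partition_classes(labels, n_folds = 3, equalize = TRUE)
  # classes subsampled to 60: the C class drops 10 epochs
  expect_equal(sum(!is.na(fold)), 240)
  for (cl in c("E", "F", "A", "C")) {
    f <- fold[labels == cl]
    expect_equal(sum(!is.na(f)), 60)
    expect_equal(as.vector(table(f[!is.na(f)])), rep(20L, 3))  # 20 per fold
  }
  # 3 epochs per class, 3 folds: one per class per fold
  lab3 <- rep(c("E", "F", "A", "C"), 3)
  set.seed(1)
  f3 <- partition_classes(lab3, 3)
  for (cl in c("E", "F", "A", "C"))
    expect_setequal(f3[lab3 == cl], 1:3)
  # determinism under a fixed RNG state
  set.seed(77); a <- partition_classes(labels, 3)
  set.seed(77); b <- partition_classes(labels, 3)
  expect_identical(a, b)
  # every kept epoch is tested exactly once per iteration (fold-exhaustive)
  expect_true(all(table(a[!is.na(a)]) > 0))
  expect_error(partition_classes(c("E", "E", "F"), 3), "fewer epochs")
})

test_that("decode_timepoint separates separable classes and matches a
           hand-computed margin assignment", {
  # four classes at widely separated 34-dim means, no noise
  set.seed(4)
  mu <- matrix(rnorm(4 * 34, sd = 10), 4)
  Xtr <- mu[rep(1:4, each = 3), ] + rnorm(12 * 34, sd = 0.01)
  ytr <- rep(c("E", "F", "A", "C"), each = 3)
  expect_equal(decode_timepoint(Xtr, ytr, mu, c("E", "F", "A", "C")), 1)
  # 2-observation-per-class toy problem in 2 dimensions: classes separated
  # on x; the max-margin boundary is x = 0, so signs of x decide
  Xt <- rbind(c(1, 0), c(1, 1), c(-1, 0), c(-1, 1))
  yt <- c("E", "E", "F", "F")
  te <- rbind(c(0.2, 5), c(-0.2, -5), c(3, 0), c(-3, 0))
  expect_equal(decode_timepoint(Xt, yt, te, c("E", "F", "E", "F")), 1)
  expect_equal(decode_timepoint(Xt, yt, te, c("F", "E", "F", "E")), 0)
  expect_error(decode_timepoint(Xt[1:2, ], c("E", "E"), te, yt),
               "single-class")
})

test_that("label-shuffled pure-noise decoding sits at chance", {
  # class-balanced train/test splits, as in the cross-validation scheme
  # (unbalanced small-sample CV is pessimistically biased by construction)
  set.seed(6)
  y <- rep(c("E", "F", "A", "C"), each = 4)
  acc <- replicate(300, {
    X <- matrix(rnorm(16 * 8), 16)
    tr <- as.vector(vapply(0:3, function(k) 4 * k + sample(4, 3), numeric(3)))
    decode_timepoint(X[tr, ], y[tr], X[-tr, ], y[-tr])
  })
  # binomial null: 300 x 4 test observations, 95% CI around 0.25
  expect_lt(abs(mean(acc) - 0.25), 1.96 * sqrt(0.25 * 0.75 / 1200) + 0.005)
})

test_that("decode_timecourse finds injected structure where it was put", {
  cfg <- simulation_config(noise_sd = 4,
                           note_pattern_amp = c(familiar = 1.5, unfamiliar = 0),
                           artifact_fraction = 0, seed = 5)
  sch <- tiny_schedule(presentations = 12, seed = 5)   # 48 omissions/cond
  res <- simulate_participant(sch, cfg, 19)
  dcfg <- decode_config(n_iterations = 4, decimation_ms = 10, seed = 3)
  fam <- decode_timecourse(preprocess_epochs(res$epochs$familiar), dcfg)
  unf <- decode_timecourse(preprocess_epochs(res$epochs$unfamiliar), dcfg)
  expect_gt(window_mean_accuracy(fam, c(50, 90)), 0.5)
  # outside the injected window (well clear of filter smearing)
  expect_lt(window_mean_accuracy(fam, c(-200, 0)), 0.4)
  expect_lt(abs(window_mean_accuracy(unf, c(50, 90)) - 0.25), 0.15)
  expect_equal(fam$chance, 0.25)
  expect_true(all(fam$accuracy >= 0 & fam$accuracy <= 1))
})

test_that("noiseless duplicates leave the accuracy series unchanged", {
  # with identical trials per class, any block average equals the trial, so
  # duplicating every trial cannot change the series
  time <- seq(-200, 300)
  set.seed(8)
  proto <- lapply(c(E = 1, F = 2, A = 3, C = 4), function(k)
    matrix(rnorm(501 * 4, sd = 0.1), 501, 4))
  mk <- function(reps) {
    labs <- rep(rep(c("E", "F", "A", "C"), each = 3), reps)
    manual_epoch_set(rep(lapply(labs[1:12], function(l) proto[[l]]), reps),
                     time = time, labels = labs)
  }
  dcfg <- decode_config(n_iterations = 2, decimation_ms = 50, seed = 9)
  a1 <- decode_timecourse(mk(1), dcfg)
  a2 <- decode_timecourse(mk(2), dcfg)
  expect_equal(a1$accuracy, a2$accuracy)
})

test_that("all-zero data decodes at exactly chance", {
  time <- seq(-200, 300)
  es <- manual_epoch_set(rep(list(matrix(0, 501, 4)), 12), time = time,
                         labels = rep(c("E", "F", "A", "C"), 3))
  a <- decode_timecourse(es, decode_config(n_iterations = 2,
                                           decimation_ms = 100, seed = 1))
  expect_true(all(abs(a$accuracy - 0.25) < 1e-12))
})

test_that("window accuracy increases monotonically with pattern amplitude", {
  sch <- tiny_schedule(presentations = 9, seed = 6)    # 36 omissions/cond
  accs <- vapply(c(0, 0.6, 2.5), function(amp) {
    cfg <- simulation_config(noise_sd = 4, artifact_fraction = 0,
                             note_pattern_amp = c(familiar = amp,
                                                  unfamiliar = 0), seed = 2)
    res <- simulate_participant(sch, cfg, 31)
    a <- decode_timecourse(preprocess_epochs(res$epochs$familiar),
                           decode_config(n_iterations = 3, decimation_ms = 10,
                                         seed = 7))
    window_mean_accuracy(a, c(50, 90))
  }, 0)
  expect_equal(cor(accs, 1:3, method = "spearman"), 1)  # rank correlation 1
})

test_that("window_mean_accuracy is an inclusive-endpoint mean", {
  s <- structure(list(time = c(0, 10, 20, 30, 40),
                      accuracy = c(0.2, 0.3, 0.4, 0.3, 0.2),
                      chance = 0.25), class = "accuracy_series")
  expect_equal(window_mean_accuracy(s, c(0, 40)), 0.28)   # hand mean
  expect_equal(window_mean_accuracy(s, c(10, 30)), 1 / 3)
  s$accuracy <- rep(0.3, 5)
  expect_equal(window_mean_accuracy(s, c(0, 40)), 0.3)
  expect_error(window_mean_accuracy(s, c(100, 200)), "no decoded")
})
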