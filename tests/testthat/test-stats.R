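# Expected values marked "reported" below were checked against the study's
# printed statistics before being frozen here.

test_that("dz reproduces the reported effect sizes from t and n", {
  # dz = t / sqrt(n): -3.67/sqrt(25) = -0.734; 3.10/sqrt(24) = 0.633;
  # -0.72/sqrt(24) = -0.147 -> printed -0.73, 0.63, -0.15
  expect_equal(round(-3.67 / sqrt(25), 2), -0.73)
  set.seed(1)
  x <- rnorm(25); y <- rnorm(25)
  r <- paired_t_dz(x, y)
  expect_equal(r$dz, r$t / sqrt(r$n), tolerance = 1e-12)
  expect_equal(r$df, 24)
  r2 <- one_sample_t_dz(rnorm(24), mu = 0.25)
  expect_equal(r2$dz, r2$t / sqrt(24), tolerance = 1e-12)
})

test_that("paired t matches a brute-force oracle on toy data", {
  x <- c(2.0, 3.5, 1.2, 4.4, 2.9)
  y <- c(1.1, 3.0, 1.5, 3.9, 2.2)
  d <- x - y
  r <- paired_t_dz(x, y)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4), tolerance = 1e-12)
  expect_equal(r$dz, mean(d) / sd(d), tolerance = 1e-12)
  # x == y -> zero variance of differences is an error (t undefined)
  expect_error(paired_t_dz(x, x), "zero-variance")
  # closed form: x = mu + c with sd s -> t = c sqrt(n) / s
  z <- c(1, 2, 3, 4, 5) + 10
  r3 <- one_sample_t_dz(z, mu = 10)
  expect_equal(r3$t, 3 * sqrt(5) / sd(1:5), tolerance = 1e-12)
  expect_equal(r3$tail, "two")
  expect_lt(one_sample_t_dz(z, mu = 10, tail = "greater")$p, r3$p)
})

test_that("JZS Bayes factors reproduce the reported values", {
  # reported: BF10 = 29.41 (t=3.67, n=25), 8.67 (3.10, 24), 0.27 (-0.72, 24);
  # reproduction from rounded printed t carries ~3% slack
  expect_lt(abs(jzs_bf10(3.67, 25)$bf10 - 29.41) / 29.41, 0.03)
  expect_lt(abs(jzs_bf10(3.10, 24)$bf10 - 8.67) / 8.67, 0.03)
  expect_lt(abs(jzs_bf10(-0.72, 24)$bf10 - 0.27) / 0.27, 0.03)
})

test_that("JZS Bayes factor properties: sign symmetry, monotonicity, null", {
  b <- jzs_bf10(2.2, 20)
  expect_equal(b$bf01, 1 / b$bf10, tolerance = 1e-12)
  expect_equal(jzs_bf10(-2.2, 20)$bf10, b$bf10, tolerance = 1e-9)
  # strictly increasing in |t| for fixed n, r
  ts <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, function(t) jzs_bf10(t, 25)$bf10, 0)
  expect_true(all(diff(bfs) > 0))
  # evidence for the null at t = 0
  expect_lt(jzs_bf10(0, 25)$bf10, 1)
  expect_lt(jzs_bf10(0, 2)$bf10, 1)
  expect_error(jzs_bf10(2, 1), "n >= 2")
})

test_that("power analysis reproduces the predetermined sample size", {
  # reported: n = 21 for dz = 0.66, alpha = 0.05, power = 0.80
  r <- power_sample_size(0.66, 0.05, 0.80)
  expect_equal(r$n_required, 21)
  # bracketing: power(n-1) < target <= power(n)
  expect_gte(r$achieved_power, 0.80)
  expect_lt(t_test_power(0.66, 20), 0.80)
  # monotonicity: doubling dz never increases n
  expect_lte(power_sample_size(1.32)$n_required, 21)
  ns <- vapply(c(0.3, 0.5, 0.8, 1.2), function(d)
    power_sample_size(d)$n_required, 0L)
  expect_true(all(diff(ns) < 0))
})

test_that("power at the returned n agrees with a Monte-Carlo oracle", {
  r <- power_sample_size(0.5, 0.05, 0.80)
  mc_power <- function(n, dz, reps = 20000) {
    set.seed(99)
    X <- matrix(rnorm(n * reps, mean = dz), n)
    m <- colMeans(X)
    s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
    mean(abs(m / (s / sqrt(n))) > qt(0.975, n - 1))
  }
  se <- sqrt(0.8 * 0.2 / 20000)
  expect_gte(mc_power(r$n_required, 0.5), 0.80 - 3 * se)
  expect_lt(mc_power(r$n_required - 1, 0.5), 0.80 + 3 * se)
})

test_that("cluster permutation: no clusters for identical series", {
  set.seed(12)
  A <- matrix(rnorm(10 * 60), 10)
  r <- cluster_permutation(A, A, n_permutations = 100)
  expect_equal(nrow(r$clusters), 0)
  expect_equal(r$threshold, qt(0.975, 9))
})

test_that("cluster permutation localizes an injected offset", {
  t_axis <- seq(-200, 300, by = 10)
  set.seed(21)
  ok <- vapply(1:5, function(s) {
    A <- matrix(rnorm(8 * length(t_axis), sd = 0.06), 8)
    B <- matrix(rnorm(8 * length(t_axis), sd = 0.06), 8)
    sel <- t_axis >= 58 & t_axis <= 83
    A[, sel] <- A[, sel] + 0.3
    r <- cluster_permutation(A, B, time = t_axis, n_permutations = 300,
                             seed = s)
    sig <- r$clusters[r$clusters$p_perm < 0.05, , drop = FALSE]
    any(vapply(seq_len(nrow(sig)), function(i)
      jaccard_ms(sig$start_ms[i], sig$end_ms[i], 58, 83, t_axis) >= 0.8, NA))
  }, NA)
  expect_gte(sum(ok), 4)   # Jaccard >= 0.8 across (almost) all seeds
})

test_that("cluster permutation p-values are valid and sign-symmetric", {
  set.seed(30)
  A <- matrix(rnorm(6 * 40), 6) + 0.8
  B <- matrix(rnorm(6 * 40), 6)
  r <- cluster_permutation(A, B, n_permutations = 200, seed = 3)
  expect_true(all(r$clusters$p_perm >= 1 / 201 & r$clusters$p_perm <= 1))
  # swapping the inputs flips t_sum but not the two-tailed p
  r2 <- cluster_permutation(B, A, n_permutations = 200, seed = 3)
  expect_equal(r2$clusters$t_sum, -r$clusters$t_sum, tolerance = 1e-12)
  expect_equal(r2$clusters$p_perm, r$clusters$p_perm)
  # one-tailed variants restrict the reported clusters
  rg <- cluster_permutation(A, B, n_permutations = 200, seed = 3,
                            tail = "greater")
  expect_true(all(rg$clusters$t_sum > 0))
  expect_error(cluster_permutation(A, B[1:3, ]), "matching")
})
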