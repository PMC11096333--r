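test_that("noiseless construction recovers the configured amplitude exactly", {
  cfg <- tiny_sim_config(noise_sd = 0, on1_within_sd = 0,
                         artifact_fraction = 0,
                         note_pattern_amp = c(familiar = 0, unfamiliar = 0))
  sch <- tiny_schedule()
  res <- simulate_participant(sch, cfg, 1,
                              on1_amplitude = c(familiar = -2, unfamiliar = -2))
  s <- roi_mean(average_epochs(res$epochs$familiar))
  expect_equal(s$value[s$time == 109], -2)
  # every epoch identical to the expected noiseless ROI waveform
  exp_wave <- expected_roi_waveform(cfg, amplitude = -2)
  expect_equal(rowMeans(res$epochs$familiar$data[, match(frontocentral_roi(),
               cfg$channels), 1]), exp_wave$value, tolerance = 1e-12)
})

test_that("zero amplitudes and zero noise give all-zero epochs", {
  cfg <- tiny_sim_config(noise_sd = 0, on1_within_sd = 0,
                         artifact_fraction = 0,
                         note_pattern_amp = c(familiar = 0, unfamiliar = 0))
  res <- simulate_participant(tiny_schedule(), cfg, 1,
                              on1_amplitude = c(familiar = 0, unfamiliar = 0))
  expect_true(all(res$epochs$familiar$data == 0))
  expect_true(all(res$epochs$unfamiliar$data == 0))
})

test_that("epoch sets carry consistent axes, labels and counts", {
  cfg <- tiny_sim_config()
  sch <- tiny_schedule()
  res <- simulate_participant(sch, cfg, 3)
  es <- res$epochs$familiar
  expect_equal(dim(es$data)[3],
               sum(sch$omitted & sch$condition == "familiar"))
  expect_equal(diff(es$time), rep(1, length(es$time) - 1))
  expect_true(all(es$labels %in% c("E", "F", "A", "C")))
  expect_equal(es$labels,
               sch$note[sch$omitted & sch$condition == "familiar"])
  expect_equal(range(es$time), c(-400, 400))
})

test_that("artifact bookkeeping: flagged fraction and raw threshold crossing", {
  cfg <- simulation_config(artifact_fraction = 0.1, noise_sd = 2)
  sch <- build_schedule(seed = 4)       # 250 omissions per condition
  res <- simulate_participant(sch, cfg, 6)
  idx <- res$truth$conditions$familiar$artifact_epochs
  expect_length(idx, 25)                # 0.1 x 250
  d <- dim(res$epochs$familiar$data)
  X <- res$epochs$familiar$data
  dim(X) <- c(d[1] * d[2], d[3])
  peaks <- apply(abs(X), 2, max)
  expect_true(all(peaks[idx] > 80))
  expect_true(all(peaks[-idx] < 80))
})

test_that("linearity: zeroing the note patterns removes exactly their part", {
  sch <- tiny_schedule()
  amp <- c(familiar = -1.5, unfamiliar = -1.5)
  cfg1 <- tiny_sim_config(note_pattern_amp = c(familiar = 2, unfamiliar = 0),
                          artifact_fraction = 0)
  cfg0 <- tiny_sim_config(note_pattern_amp = c(familiar = 0, unfamiliar = 0),
                          artifact_fraction = 0)
  r1 <- simulate_participant(sch, cfg1, 8, on1_amplitude = amp)
  r0 <- simulate_participant(sch, cfg0, 8, on1_amplitude = amp)
  diffarr <- r1$epochs$familiar$data - r0$epochs$familiar$data
  g <- as.numeric(r1$epochs$familiar$time >= 50 &
                  r1$epochs$familiar$time <= 90)
  for (i in seq_len(dim(diffarr)[3])) {
    pat <- 2 * r1$truth$note_patterns[, r1$epochs$familiar$labels[i]]
    expect_equal(diffarr[, , i], outer(g, unname(pat)), tolerance = 1e-12)
  }
  # unfamiliar condition has zero pattern amplitude in both configs
  expect_equal(r1$epochs$unfamiliar$data, r0$epochs$unfamiliar$data)
})

test_that("cohort determinism and degenerate between-SD", {
  sch <- tiny_schedule(presentations = 2)
  cfg <- tiny_sim_config(n_participants = 3, seed = 21,
                         on1_between_sd = c(familiar = 0, unfamiliar = 0))
  a <- simulate_cohort(cfg, sch)
  b <- simulate_cohort(cfg, sch)
  expect_identical(a$participants[[2]]$epochs$familiar$data,
                   b$participants[[2]]$epochs$familiar$data)
  # zero between-SD: every participant's true amplitude equals the mean
  expect_true(all(a$truth$on1_amplitudes[, "familiar"] == -1.95))
  expect_true(all(a$truth$on1_amplitudes[, "unfamiliar"] == -1.37))
})

test_that("between-participant SD is recovered across a large cohort", {
  # Monte-Carlo check of the sampling distribution: n = 100 draws, SD 1.17
  sch <- build_schedule(list(melody_spec("m", "familiar", c(E = 2)),
                             melody_spec("ms", "unfamiliar", c(E = 2))),
                        presentations_per_melody = 1, seed = 3)
  cfg <- simulation_config(
    n_participants = 100, noise_sd = 0, on1_within_sd = 0,
    artifact_fraction = 0,
    on1_between_sd = c(familiar = 1.17, unfamiliar = 0.98), seed = 33)
  co <- simulate_cohort(cfg, sch)
  expect_lt(abs(sd(co$truth$on1_amplitudes[, "familiar"]) - 1.17) / 1.17, 0.2)
  expect_lt(abs(sd(co$truth$on1_amplitudes[, "unfamiliar"]) - 0.98) / 0.98, 0.2)
})

test_that("background noise has the configured 1/f spectral slope", {
  cfg <- tiny_sim_config(noise_sd = 5, on1_within_sd = 0,
                         artifact_fraction = 0, noise_exponent = 1,
                         note_pattern_amp = c(familiar = 0, unfamiliar = 0))
  sch <- tiny_schedule(presentations = 10, seed = 2)   # 40 epochs/condition
  res <- simulate_participant(sch, cfg, 13,
                              on1_amplitude = c(familiar = 0, unfamiliar = 0))
  X <- res$epochs$familiar$data
  d <- dim(X)
  n <- d[1]
  freqs <- (seq_len(n) - 1) / n * cfg$fs
  sel <- freqs >= 2 & freqs <= 40
  dim(X) <- c(n, d[2] * d[3])
  pgram <- rowMeans(abs(stats::mvfft(X))^2)[sel] / n
  fit <- stats::lm(log(pgram) ~ log(freqs[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) - (-1)), 0.25)
})

test_that("config validation catches inconsistent parameters", {
  expect_error(simulation_config(fs = 0), "fs")
  expect_error(simulation_config(epoch_span = c(-100, 400)), "epoch_span")
  expect_error(simulation_config(noise_sd = -1), "negative variances")
  expect_error(simulation_config(artifact_fraction = 0.1, artifact_amp = 50),
               "80 uV")
  expect_error(simulation_config(channels = c("Fz", "Nope")), "montage")
  expect_error(simulation_config(on1_mean = c(familiar = -2)), "unfamiliar")
})

test_that("epoch sets round-trip through the text container", {
  cfg <- tiny_sim_config()
  sch <- build_schedule(tiny_specs(), 1, 0.5, seed = 2)
  es <- simulate_participant(sch, cfg, 5)$epochs$familiar
  es <- crop_epochs(es, c(-50, 50))     # keep the fixture small
  prefix <- file.path(withr::local_tempdir(), "ep")
  write_epoch_set(es, prefix)
  back <- read_epoch_set(prefix)
  expect_equal(back$data, es$data, tolerance = 1e-12)
  expect_equal(back$labels, es$labels)
  expect_equal(back$time, es$time)
  expect_equal(back$retained, es$retained)
  expect_equal(back$provenance, es$provenance)
})
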