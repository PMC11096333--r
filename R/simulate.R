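#' Simulation configuration
#'
#' Parameters of the forward model that generates synthetic omission epochs.
#' Defaults encode the study conditions the package emulates: 1000 Hz
#' sampling, 34-channel 10-20 montage, a frontocentral negative component
#' peaking at 109 ms whose population means are -1.95 uV (familiar) and
#' -1.37 uV (unfamiliar), between-participant SDs of 1.1/1.0 uV with
#' correlation 0.85 across conditions (implied by the reported per-condition
#' SDs together with the reported paired effect size; see the methods
#' vignette), note-identity-specific spatial patterns confined to 50-90 ms
#' and present only in the familiar condition, 1/f spatially correlated
#' background noise, and occasional large frontal artifact transients that
#' exceed the +-80 uV rejection threshold.
#'
#' @param n_participants cohort size (default 25).
#' @param fs sampling rate, Hz.
#' @param epoch_span generated epoch limits in ms (wider than the analysis
#'   window so zero-phase filtering has padding).
#' @param channels channel names (default: the standard 34-channel montage).
#' @param on1_mean named condition means of the oN1 peak amplitude, uV.
#' @param on1_between_sd named condition between-participant SDs, uV.
#' @param on1_between_corr correlation of participant-level amplitudes across
#'   conditions.
#' @param on1_within_sd trial-to-trial amplitude jitter SD, uV.
#' @param on1_peak_ms latency of the component peak, ms.
#' @param on1_halfwidth_ms half-width of the Hann temporal kernel, ms.
#' @param on1_topography named channel weights; mean over `roi` must be 1 so
#'   the ROI-mean waveform recovers the configured amplitude.
#' @param note_pattern_amp named condition amplitudes of the note-specific
#'   patterns, uV.
#' @param note_pattern_window_ms boxcar window of the note patterns, ms.
#' @param noise_sd per-channel background noise SD, uV.
#' @param noise_exponent 1/f spectral exponent of the background noise.
#' @param noise_corr_length spatial correlation length of the noise (head
#'   radius units).
#' @param noise_max_hz upper frequency of noise synthesis; everything above
#'   the analysis band is irrelevant after the 25 Hz low-pass, so synthesis
#'   is band-limited for speed (documented simplification).
#' @param artifact_fraction fraction of epochs carrying an artifact.
#' @param artifact_amp artifact transient amplitude, uV (must exceed the
#'   80 uV rejection threshold when `artifact_fraction > 0`).
#' @param artifact_tau_ms artifact decay time constant, ms.
#' @param roi channels over which the topography is normalized.
#' @param seed master seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 25,
                              fs = 1000,
                              epoch_span = c(-400, 400),
                              channels = standard_montage()$channel,
                              on1_mean = c(familiar = -1.95, unfamiliar = -1.37),
                              on1_between_sd = c(familiar = 1.1, unfamiliar = 1.0),
                              on1_between_corr = 0.85,
                              on1_within_sd = 1.0,
                              on1_peak_ms = 109,
                              on1_halfwidth_ms = 25,
                              on1_topography = NULL,
                              note_pattern_amp = c(familiar = 0.3, unfamiliar = 0),
                              note_pattern_window_ms = c(50, 90),
                              noise_sd = 6,
                              noise_exponent = 1,
                              noise_corr_length = 0.35,
                              noise_max_hz = 45,
                              artifact_fraction = 0.03,
                              artifact_amp = 200,
                              artifact_tau_ms = 100,
                              roi = frontocentral_roi(),
                              seed = 1L) {
  if (fs <= 0) stop("config error: fs must be positive")
  if (epoch_span[1] > -200 || epoch_span[2] < 300)
    stop("config error: epoch_span must cover at least -200..300 ms")
  if (any(c(on1_between_sd, on1_within_sd, noise_sd) < 0))
    stop("config error: negative variances")
  if (abs(on1_between_corr) > 1)
    stop("config error: |on1_between_corr| must be <= 1")
  if (artifact_fraction > 0 && artifact_amp <= 80)
    stop("config error: artifact_amp must exceed the 80 uV rejection threshold")
  if (is.null(on1_topography)) {
    mont <- standard_montage()
    mont <- mont[match(channels, mont$channel), , drop = FALSE]
    if (any(is.na(mont$channel)))
      stop("config error: channels not in the standard montage need an ",
           "explicit on1_topography")
    on1_topography <- on1_topography(mont, roi = roi)
  }
  if (!all(channels %in% names(on1_topography)))
    stop("config error: topography does not cover all channels")
  on1_topography <- on1_topography[channels]
  if (sum(abs(on1_topography)) <= 0)
    stop("config error: topography is identically zero")
  for (v in list(on1_mean, on1_between_sd, note_pattern_amp))
    if (!all(c("familiar", "unfamiliar") %in% names(v)))
      stop("config error: condition-keyed parameters need familiar and ",
           "unfamiliar entries")
  structure(list(
    n_participants = n_participants, fs = fs, epoch_span = epoch_span,
    channels = channels, on1_mean = on1_mean,
    on1_between_sd = on1_between_sd, on1_between_corr = on1_between_corr,
    on1_within_sd = on1_within_sd, on1_peak_ms = on1_peak_ms,
    on1_halfwidth_ms = on1_halfwidth_ms, on1_topography = on1_topography,
    note_pattern_amp = note_pattern_amp,
    note_pattern_window_ms = note_pattern_window_ms,
    noise_sd = noise_sd, noise_exponent = noise_exponent,
    noise_corr_length = noise_corr_length, noise_max_hz = noise_max_hz,
    artifact_fraction = artifact_fraction, artifact_amp = artifact_amp,
    artifact_tau_ms = artifact_tau_ms, roi = roi, seed = as.integer(seed)),
    class = "simulation_config")
}

sim_time_axis <- function(config)
  seq(config$epoch_span[1], config$epoch_span[2], by = 1000 / config$fs)

#' Hann temporal kernel of the omission component
#'
#' Unit-peak raised-cosine bump centred at `peak_ms` with compact support
#' `peak_ms +- halfwidth_ms`.
#'
#' @param time time axis, ms.
#' @param peak_ms peak latency, ms.
#' @param halfwidth_ms kernel half-width, ms.
#' @return Numeric vector on `time`.
#' @export
on1_kernel <- function(time, peak_ms = 109, halfwidth_ms = 25) {
  u <- (time - peak_ms) / halfwidth_ms
  ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
}

note_pattern_kernel <- function(time, window) {
  as.numeric(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
}

# Band-limited stationary noise via a random cosine series. Coefficient
# variances follow f^(-exponent) up to noise_max_hz; channels are mixed with
# the squared-exponential spatial kernel. Returns n_samples x n_ch x n_ep.
simulate_noise <- function(n_ep, config) {
  time <- sim_time_axis(config)
  n <- length(time)
  n_ch <- length(config$channels)
  if (config$noise_sd == 0)
    return(array(0, dim = c(n, n_ch, n_ep)))
  period_s <- n / config$fs
  k_max <- max(1L, floor(config$noise_max_hz * period_s))
  f <- seq_len(k_max) / period_s
  w <- f^(-config$noise_exponent)
  sig <- config$noise_sd * sqrt(w / sum(w))        # per cos/sin coefficient
  omega <- 2 * pi * f / 1000                        # rad per ms
  B <- cbind(cos(outer(time, omega)), sin(outer(time, omega)))
  mont <- standard_montage()
  mont <- mont[match(config$channels, mont$channel), , drop = FALSE]
  U <- chol(noise_spatial_correlation(mont, config$noise_corr_length))
  nk <- 2L * k_max
  G <- matrix(rnorm(nk * n_ep * n_ch), nrow = nk * n_ep, ncol = n_ch)
  G <- G * rep(c(sig, sig), n_ep)
  G <- G %*% U                                      # rows ~ corr K
  Carr <- aperm(array(G, dim = c(nk, n_ep, n_ch)), c(1, 3, 2))
  X <- B %*% matrix(Carr, nrow = nk)
  array(X, dim = c(n, n_ch, n_ep))
}

#' Simulate one participant's omission epochs
#'
#' Every omission trial in the schedule becomes one epoch equal to the sum of
#' (i) spatially correlated 1/f background noise, (ii) the oN1 component
#' (fixed frontocentral topography times a Hann kernel, trial amplitude
#' normally jittered around the participant's condition amplitude), (iii) a
#' note-identity-specific pattern (a per-note spatial topography drawn once
#' per participant, unit RMS across channels, times a boxcar kernel and the
#' condition's pattern amplitude) and (iv), in a random subset of epochs, a
#' decaying frontal transient exceeding the rejection threshold. All
#' bookkeeping needed for parameter-recovery tests is returned as ground
#' truth, recorded before any processing.
#'
#' @param schedule an `experiment_schedule`.
#' @param config a [simulation_config()].
#' @param participant_seed integer seed for this participant.
#' @param participant_id identifier.
#' @param on1_amplitude optional named vector `c(familiar=, unfamiliar=)` of
#'   the participant's true condition amplitudes; drawn from the
#'   between-participant distribution when `NULL`.
#' @return list with `epochs` (named list of `epoch_set`, one per condition)
#'   and `truth` (ground-truth record).
#' @export
simulate_participant <- function(schedule, config, participant_seed,
                                 participant_id = "P01",
                                 on1_amplitude = NULL) {
  set.seed(participant_seed)
  conditions <- unique(schedule$condition)
  if (is.null(on1_amplitude)) {
    on1_amplitude <- draw_participant_amplitudes(1, config)[1, ]
  }
  time <- sim_time_axis(config)
  n_ch <- length(config$channels)
  notes <- c("E", "F", "A", "C")
  P <- matrix(rnorm(n_ch * 4), n_ch, 4,
              dimnames = list(config$channels, notes))
  P <- sweep(P, 2, sqrt(colMeans(P^2)), "/")       # unit RMS per note
  h <- on1_kernel(time, config$on1_peak_ms, config$on1_halfwidth_ms)
  g <- note_pattern_kernel(time, config$note_pattern_window_ms)
  topo <- config$on1_topography

  epochs <- list()
  truth_cond <- list()
  for (cond in conditions) {
    lab <- schedule$note[schedule$omitted & schedule$condition == cond]
    n_ep <- length(lab)
    if (n_ep == 0) stop("schedule has no omission trials for ", cond)
    X <- simulate_noise(n_ep, config)
    d3 <- dim(X)
    amp <- rnorm(n_ep, mean = on1_amplitude[[cond]], sd = config$on1_within_sd)
    p_amp <- config$note_pattern_amp[[cond]]
    # all deterministic components enter through one rank-5 update:
    # columns of comps are flattened channel x time patterns, rows of W the
    # per-epoch weights (oN1 trial amplitude; 0/1 note indicators)
    comps <- cbind(as.vector(outer(h, topo)),
                   vapply(notes, function(note)
                     as.vector(outer(g, P[, note] * p_amp)),
                     numeric(d3[1] * d3[2])))
    W <- cbind(amp, 1 * outer(lab, notes, "=="))
    dim(X) <- c(d3[1] * d3[2], n_ep)
    X <- X + comps %*% t(W)
    dim(X) <- d3
    art_idx <- integer(0)
    if (config$artifact_fraction > 0) {
      k <- round(config$artifact_fraction * n_ep)
      if (k > 0) {
        art_idx <- sort(sample.int(n_ep, k))
        art_ch <- match(intersect(c("Fp1", "Fp2", "F7", "F8"), config$channels),
                        config$channels)
        wch <- rep(0, n_ch); wch[art_ch] <- c(1, 1, 0.6, 0.6)[seq_along(art_ch)]
        for (i in art_idx) {
          t0 <- sample(time[time >= -100 & time <= 200], 1)
          a <- ifelse(time >= t0,
                      config$artifact_amp * exp(-(time - t0) / config$artifact_tau_ms),
                      0) * sample(c(-1, 1), 1)
          X[, , i] <- X[, , i] + outer(a, wch)
        }
      }
    }
    epochs[[cond]] <- epoch_set(X, time, config$channels, lab, config$fs,
                                condition = cond,
                                participant_id = participant_id,
                                provenance = "simulate")
    truth_cond[[cond]] <- list(trial_on1_amplitudes = amp,
                               artifact_epochs = art_idx,
                               n_epochs = n_ep)
  }
  truth <- list(participant_id = participant_id,
                on1_amplitude = unlist(on1_amplitude),
                note_patterns = P,
                note_pattern_amp = config$note_pattern_amp,
                conditions = truth_cond,
                participant_seed = participant_seed)
  list(epochs = epochs, truth = truth)
}

draw_participant_amplitudes <- function(n, config) {
  sds <- config$on1_between_sd[c("familiar", "unfamiliar")]
  rho <- config$on1_between_corr
  z1 <- rnorm(n); z2 <- rnorm(n)
  out <- cbind(
    familiar = config$on1_mean[["familiar"]] + sds[[1]] * z1,
    unfamiliar = config$on1_mean[["unfamiliar"]] +
      sds[[2]] * (rho * z1 + sqrt(1 - rho^2) * z2))
  out
}

#' Simulate a cohort
#'
#' Draws participant-level condition amplitudes from the between-participant
#' distribution (bivariate normal across conditions), derives one seed per
#' participant from the master seed, and simulates each participant.
#'
#' @param config a [simulation_config()].
#' @param schedule an `experiment_schedule`.
#' @return list with `participants` (list of [simulate_participant()]
#'   results) and `truth` (cohort-level ground truth: amplitude matrix and
#'   seeds).
#' @export
simulate_cohort <- function(config, schedule) {
  stopifnot(config$n_participants >= 1)
  set.seed(config$seed)
  amps <- draw_participant_amplitudes(config$n_participants, config)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  participants <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    participants[[i]] <- simulate_participant(
      schedule, config, participant_seed = seeds[i], participant_id = ids[i],
      on1_amplitude = amps[i, ])
  }
  names(participants) <- ids
  list(participants = participants,
       truth = list(on1_amplitudes = amps, seeds = seeds, ids = ids))
}

#' Expected noiseless ROI waveform
#'
#' The ROI-mean time course implied by the ground truth for a unit (or given)
#' oN1 amplitude, before any filtering: amplitude times the Hann kernel,
#' because the topography is normalized to ROI mean weight 1. Note patterns
#' have zero expectation over their random topographies and are excluded.
#'
#' @param config a [simulation_config()].
#' @param amplitude oN1 amplitude, uV.
#' @return list with `time` and `value`.
#' @export
expected_roi_waveform <- function(config, amplitude = 1) {
  time <- sim_time_axis(config)
  list(time = time,
       value = amplitude * on1_kernel(time, config$on1_peak_ms,
                                      config$on1_halfwidth_ms))
}

#' Pipeline gain of the oN1 window measurement
#'
#' Runs a single noiseless, unit-amplitude oN1 epoch through the exact
#' preprocessing used for data (band-pass filter, crop, baseline) and returns
#' the ROI mean amplitude over the measurement window. Dividing a measured
#' window amplitude by this factor converts it back to the generator's peak
#' amplitude scale; it accounts for both the window-averaging of the Hann
#' kernel and the filter's passband shaping.
#'
#' @param config a [simulation_config()].
#' @param pre_config a [preprocess_config()].
#' @param window measurement window (ms pair); defaults to the peak +- 10 ms.
#' @return scalar gain (window-mean amplitude per unit peak amplitude).
#' @export
on1_measurement_gain <- function(config, pre_config = preprocess_config(),
                                 window = NULL) {
  time <- sim_time_axis(config)
  h <- on1_kernel(time, config$on1_peak_ms, config$on1_halfwidth_ms)
  X <- array(outer(h, config$on1_topography), dim = c(length(time),
             length(config$channels), 1))
  es <- epoch_set(X, time, config$channels, "E", config$fs,
                  condition = "gain", participant_id = "unit")
  es <- bandpass_filter(es, pre_config$band, pre_config$transition_bw)
  es <- crop_epochs(es, pre_config$analysis_window)
  es <- baseline_correct(es, pre_config$baseline_window)
  erp <- average_epochs(es)
  series <- roi_mean(erp, pre_config$roi)
  if (is.null(window))
    window <- c(config$on1_peak_ms - 10, config$on1_peak_ms + 10)
  mean_amplitude(series, window)
}
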