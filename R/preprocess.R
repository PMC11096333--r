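#' Preprocessing configuration
#'
#' @param band band-pass edges, Hz (default 0.5-25).
#' @param transition_bw FIR transition bandwidth, Hz. The Hamming design rule
#'   (kernel length about `3.3 / (transition_bw / fs)`) maps the default
#'   6.25 Hz (25% of the upper passband edge) to a 529-tap kernel at 1000 Hz,
#'   the sharpest design whose mirror padding fits an 800 ms epoch. A
#'   continuous-recording pipeline would use a narrower low-frequency
#'   transition; on epoched data the high-pass serves only to remove DC and
#'   slow drift, which this design does exactly (the kernel has a true null
#'   at 0 Hz).
#' @param rejection_threshold absolute-amplitude rejection threshold, uV.
#' @param baseline_window baseline interval, ms.
#' @param analysis_window epoch crop interval, ms.
#' @param roi frontocentral measurement channels.
#' @param min_trials_per_class decoding inclusion floor per note class.
#' @param min_retention_fraction decoding inclusion retention floor.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(0.5, 25),
                              transition_bw = 6.25,
                              rejection_threshold = 80,
                              baseline_window = c(-200, 0),
                              analysis_window = c(-200, 300),
                              roi = frontocentral_roi(),
                              min_trials_per_class = 50,
                              min_retention_fraction = 0.8) {
  stopifnot(band[1] < band[2], band[1] >= 0, transition_bw > 0,
            rejection_threshold > 0)
  if (baseline_window[1] < analysis_window[1] ||
      baseline_window[2] > analysis_window[2])
    stop("baseline window must lie within the analysis window")
  structure(list(band = band, transition_bw = transition_bw,
                 rejection_threshold = rejection_threshold,
                 baseline_window = baseline_window,
                 analysis_window = analysis_window, roi = roi,
                 min_trials_per_class = min_trials_per_class,
                 min_retention_fraction = min_retention_fraction),
            class = "preprocess_config")
}

#' Hamming windowed-sinc band-pass kernel
#'
#' Classic windowed-sinc design: the band-pass is the difference of two
#' Hamming-windowed low-pass kernels with -6 dB cutoffs at the band edges.
#' Kernel length follows the Hamming design rule
#' `L = 3.3 / (transition_bw / fs)`, rounded up to an odd integer. Both
#' low-pass halves are normalized to unit DC gain, so the band-pass has an
#' exact null at 0 Hz. A low edge of 0 yields a pure low-pass.
#'
#' @param band passband edges, Hz.
#' @param fs sampling rate, Hz.
#' @param transition_bw transition bandwidth, Hz.
#' @return numeric kernel of odd length with attributes `band`, `fs`.
#' @export
design_fir_kernel <- function(band, fs, transition_bw = 6.25) {
  L <- ceiling(3.3 / (transition_bw / fs))
  if (L %% 2 == 0) L <- L + 1
  m <- (L - 1) / 2
  k <- -m:m
  win <- 0.54 + 0.46 * cos(pi * k / m)
  lowpass <- function(fc) {
    h <- 2 * fc / fs * sinc(2 * fc / fs * k) * win
    h / sum(h)
  }
  h <- if (band[1] <= 0) lowpass(band[2]) else lowpass(band[2]) - lowpass(band[1])
  attr(h, "band") <- band
  attr(h, "fs") <- fs
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Frequency response of an FIR kernel
#'
#' Direct evaluation of the (real, zero-phase) transfer function at the
#' requested frequencies; used as the design oracle in tests.
#'
#' @param h kernel from [design_fir_kernel()].
#' @param freqs frequencies, Hz.
#' @param fs sampling rate, Hz (taken from the kernel if present).
#' @return numeric gains.
#' @export
fir_response <- function(h, freqs, fs = attr(h, "fs")) {
  m <- (length(h) - 1) / 2
  k <- -m:m
  vapply(freqs, function(f) sum(h * cos(2 * pi * f / fs * k)), 0)
}

#' Zero-phase band-pass filter an epoch set
#'
#' Applies the Hamming windowed-sinc band-pass to every channel of every
#' epoch with mirror padding, via a single-pass FFT convolution of the
#' symmetric (hence zero-phase, no group delay) kernel. Output has the same
#' shape as the input. Errors when the epoch is too short to provide the
#' `(L-1)/2` samples of padding the kernel needs.
#'
#' @param epochs an `epoch_set`.
#' @param band passband edges, Hz.
#' @param transition_bw transition bandwidth, Hz.
#' @return filtered `epoch_set`.
#' @export
bandpass_filter <- function(epochs, band = c(0.5, 25), transition_bw = 6.25) {
  h <- design_fir_kernel(band, epochs$fs, transition_bw)
  d <- dim(epochs$data)
  X <- epochs$data
  dim(X) <- c(d[1], d[2] * d[3])
  Y <- fir_filter_cols(X, as.numeric(h))
  dim(Y) <- d
  epochs$data <- Y
  stamp_stage(epochs, sprintf("filter[%g-%g Hz]", band[1], band[2]))
}

#' Amplitude-threshold artifact rejection
#'
#' Flags (does not delete) every epoch whose absolute voltage exceeds the
#' threshold at any channel/sample inside the window. A rejection log
#' (participant, condition, epoch, peak uV, channel) is attached as the
#' `rejection_log` attribute.
#'
#' @param epochs an `epoch_set`.
#' @param threshold uV.
#' @param window ms pair; default spans the whole current epoch.
#' @return `epoch_set` with updated `retained` flags.
#' @export
reject_artifacts <- function(epochs, threshold = 80, window = NULL) {
  if (is.null(window)) window <- range(epochs$time)
  sel <- which(epochs$time >= window[1] - 1e-9 &
               epochs$time <= window[2] + 1e-9)
  if (!length(sel)) stop("rejection window outside epoch span")
  d <- dim(epochs$data)
  pk <- epoch_peaks_cpp(epochs$data, d[1], d[2], d[3], min(sel), max(sel))
  ep_peak <- pk$peak
  ep_ch <- epochs$channels[pk$channel]
  bad <- ep_peak > threshold
  epochs$retained <- epochs$retained & !bad
  log <- data.frame(participant = rep(epochs$participant_id, sum(bad)),
                    condition = rep(epochs$condition, sum(bad)),
                    epoch = which(bad),
                    peak_uV = ep_peak[bad],
                    channel = ep_ch[bad])
  attr(epochs, "rejection_log") <- log
  stamp_stage(epochs, sprintf("reject[%g uV]", threshold))
}

#' Baseline correction
#'
#' Subtracts, per epoch and channel, the mean over the baseline window, so
#' post-event deflections are measured relative to the prestimulus level.
#'
#' @param epochs an `epoch_set`.
#' @param baseline_window ms pair.
#' @return corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-200, 0)) {
  sel <- which(epochs$time >= baseline_window[1] - 1e-9 &
               epochs$time <= baseline_window[2] + 1e-9)
  if (!length(sel)) stop("empty baseline window")
  d <- dim(epochs$data)
  epochs$data <- center_epochs_cpp(epochs$data, d[1], d[2] * d[3],
                                   min(sel), max(sel))
  stamp_stage(epochs, sprintf("baseline[%g,%g]",
                              baseline_window[1], baseline_window[2]))
}

#' Participant inclusion gate for decoding
#'
#' A participant enters the decoding analysis only if every note class keeps
#' at least `min_trials_per_class` artifact-free trials AND at least
#' `min_retention_fraction` of its scheduled trials ("less than 80% or 50
#' trials" excludes). The ERP analysis is not gated.
#'
#' @param retained named per-note retained counts.
#' @param scheduled named per-note scheduled counts.
#' @param config a [preprocess_config()].
#' @return list with `included` (logical) and `reasons` (character).
#' @export
check_inclusion <- function(retained, scheduled, config = preprocess_config()) {
  stopifnot(all(names(retained) %in% names(scheduled)))
  scheduled <- scheduled[names(retained)]
  if (any(retained > scheduled)) stop("retained counts exceed scheduled")
  reasons <- character()
  low_n <- retained < config$min_trials_per_class
  if (any(low_n))
    reasons <- c(reasons, sprintf("class %s retained %d < %d trials",
                                  names(retained)[low_n], retained[low_n],
                                  config$min_trials_per_class))
  frac <- retained / scheduled
  low_f <- frac < config$min_retention_fraction
  if (any(low_f))
    reasons <- c(reasons, sprintf("class %s retention %.2f < %.2f",
                                  names(retained)[low_f], frac[low_f],
                                  config$min_retention_fraction))
  list(included = length(reasons) == 0, reasons = reasons)
}

#' Full preprocessing chain
#'
#' Fixed stage order: band-pass filter -> (ICA slot, a documented no-op for
#' synthetic data) -> crop to the analysis window -> amplitude rejection ->
#' baseline correction. Each stage stamps the epoch-set provenance so the
#' order is verifiable.
#'
#' @param epochs an `epoch_set` (raw, from the simulator).
#' @param config a [preprocess_config()].
#' @return preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, config = preprocess_config()) {
  epochs <- bandpass_filter(epochs, config$band, config$transition_bw)
  epochs <- stamp_stage(epochs, "ica[skipped]")
  epochs <- crop_epochs(epochs, config$analysis_window)
  epochs <- reject_artifacts(epochs, config$rejection_threshold)
  epochs <- baseline_correct(epochs, config$baseline_window)
  epochs
}
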