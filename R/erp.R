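#' Average epochs into an ERP waveform
#'
#' Pointwise mean over (by default retained) epochs.
#'
#' @param epochs an `epoch_set`.
#' @param retained_only average only epochs whose retained flag is set.
#' @return object of class `erp_waveform`: list with `data`
#'   (channels x samples), `time`, `channels`, `n_epochs_averaged`,
#'   `condition`, `level`.
#' @export
average_epochs <- function(epochs, retained_only = TRUE) {
  sel <- if (retained_only) which(epochs$retained) else seq_len(n_epochs(epochs))
  if (length(sel) == 0) stop("no retained epochs to average")
  d <- dim(epochs$data)
  X <- epochs$data
  dim(X) <- c(d[1] * d[2], d[3])
  m <- matrix(X %*% replace(numeric(d[3]), sel, 1 / length(sel)),
              nrow = d[1])                          # samples x channels
  structure(list(data = t(m), time = epochs$time, channels = epochs$channels,
                 n_epochs_averaged = length(sel),
                 condition = epochs$condition, level = "participant"),
            class = "erp_waveform")
}

#' Grand-average participant ERPs
#'
#' Unweighted mean across participants' waveforms (matched time axes and
#' channel sets required).
#'
#' @param waveforms list of `erp_waveform`.
#' @return `erp_waveform` with `level = "grand"`.
#' @export
grand_average <- function(waveforms) {
  stopifnot(length(waveforms) >= 1)
  acc <- waveforms[[1]]$data * 0
  for (w in waveforms) {
    if (!isTRUE(all.equal(w$time, waveforms[[1]]$time)))
      stop("mismatched time axes")
    acc <- acc + w$data
  }
  out <- waveforms[[1]]
  out$data <- acc / length(waveforms)
  out$n_epochs_averaged <- length(waveforms)
  out$level <- "grand"
  out
}

#' ROI mean time series
#'
#' Unweighted mean across the named channels of an ERP waveform.
#'
#' @param waveform an `erp_waveform`.
#' @param roi channel names.
#' @return list of class `roi_series` with `time` and `value`.
#' @export
roi_mean <- function(waveform, roi = frontocentral_roi()) {
  missing <- setdiff(roi, waveform$channels)
  if (length(missing))
    stop("ROI channels not present: ", paste(missing, collapse = ", "))
  idx <- match(roi, waveform$channels)
  structure(list(time = waveform$time,
                 value = colMeans(waveform$data[idx, , drop = FALSE])),
            class = "roi_series")
}

#' Derive the oN1 measurement window
#'
#' The two condition grand-mean ROI series are first averaged; the component
#' peak is the most negative sample (for `polarity = "negative"`) inside the
#' search interval, ties broken toward the earliest sample; the measurement
#' window is the peak latency plus/minus `half_width`. An `edge` flag is
#' raised when the detected peak sits on a search boundary.
#'
#' @param grand_familiar,grand_unfamiliar `roi_series` on a common time axis.
#' @param search search interval, ms (default 50-110).
#' @param half_width half-width of the measurement window, ms (default 10).
#' @param polarity `"negative"` (default, oN1) or `"positive"`.
#' @return list of class `measurement_window`: `lo`, `hi`, `peak_latency`,
#'   `polarity`, `edge`.
#' @export
#' @examples
#' t <- seq(-200, 300)
#' v <- -exp(-(t - 109)^2 / 200)
#' s <- structure(list(time = t, value = v), class = "roi_series")
#' define_on1_window(s, s) # window 99-119 ms
define_on1_window <- function(grand_familiar, grand_unfamiliar,
                              search = c(50, 110), half_width = 10,
                              polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (!isTRUE(all.equal(grand_familiar$time, grand_unfamiliar$time)))
    stop("condition series must share the time axis")
  time <- grand_familiar$time
  if (search[1] - half_width < min(time) || search[2] + half_width > max(time))
    stop("search window (plus half-width) outside data span")
  combined <- (grand_familiar$value + grand_unfamiliar$value) / 2
  sel <- which(time >= search[1] - 1e-9 & time <= search[2] + 1e-9)
  v <- combined[sel]
  if (polarity == "positive") v <- -v
  peak <- time[sel[which.min(v)]]                   # which.min: earliest tie
  structure(list(lo = peak - half_width, hi = peak + half_width,
                 peak_latency = peak, polarity = polarity,
                 edge = peak <= search[1] + 1e-9 || peak >= search[2] - 1e-9),
            class = "measurement_window")
}

#' Mean amplitude over a measurement window
#'
#' Arithmetic mean of the samples with `lo <= t <= hi`, endpoints inclusive
#' (99-119 ms at 1000 Hz covers 21 samples).
#'
#' @param series a `roi_series`.
#' @param window a `measurement_window` or ms pair.
#' @return mean amplitude, uV.
#' @export
mean_amplitude <- function(series, window) {
  if (inherits(window, "measurement_window")) window <- c(window$lo, window$hi)
  sel <- series$time >= window[1] - 1e-9 & series$time <= window[2] + 1e-9
  if (!any(sel)) stop("window contains no samples")
  mean(series$value[sel])
}
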