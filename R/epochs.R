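#' Construct an epoch set
#'
#' Container for one participant x condition collection of EEG epochs.
#' Data are stored as a 3-D array of `n_samples x n_channels x n_epochs`
#' microvolt values (sample-major layout keeps per-channel time series
#' contiguous for filtering).
#'
#' @param data numeric array `n_samples x n_channels x n_epochs`.
#' @param time numeric vector of sample times in ms, strictly increasing with
#'   step `1000 / fs`.
#' @param channels character vector of channel names.
#' @param labels factor/character of note labels (E/F/A/C), one per epoch.
#' @param fs sampling rate in Hz.
#' @param condition condition label.
#' @param participant_id participant identifier.
#' @param retained logical per epoch; artifact rejection clears flags rather
#'   than deleting data.
#' @param provenance character vector of processing-stage tags.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time, channels, labels, fs,
                      condition = NA_character_,
                      participant_id = NA_character_,
                      retained = NULL, provenance = character()) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(time)) stop("time axis does not match data")
  if (dim(data)[2] != length(channels)) stop("channels do not match data")
  if (dim(data)[3] != length(labels)) stop("labels do not match epochs")
  step <- 1000 / fs
  if (length(time) > 1 &&
      max(abs(diff(time) - step)) > 1e-6)
    stop("time axis must increase in steps of 1000/fs ms")
  if (is.null(retained)) retained <- rep(TRUE, dim(data)[3])
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("E", "F", "A", "C"))
  if (length(bad)) stop("unknown note labels: ", paste(bad, collapse = ", "))
  structure(list(data = data, time = time, channels = channels,
                 labels = labels, retained = retained, fs = fs,
                 condition = condition, participant_id = participant_id,
                 provenance = provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s / %s: %d epochs x %d channels x %d samples (%g-%g ms @ %g Hz), %d retained\n",
              x$participant_id, x$condition, d[3], d[2], d[1],
              min(x$time), max(x$time), x$fs, sum(x$retained)))
  if (length(x$provenance))
    cat("  stages:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

n_epochs <- function(x) dim(x$data)[3]

stamp_stage <- function(x, tag) {
  x$provenance <- c(x$provenance, tag)
  x
}

#' Crop epochs to a time window
#'
#' @param epochs an `epoch_set`.
#' @param window length-2 numeric (ms), inclusive endpoints.
#' @return Cropped `epoch_set`.
#' @export
crop_epochs <- function(epochs, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- epochs$time >= window[1] - 1e-9 & epochs$time <= window[2] + 1e-9
  if (!any(keep)) stop("crop window outside epoch span")
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$time <- epochs$time[keep]
  stamp_stage(epochs, sprintf("crop[%g,%g]", window[1], window[2]))
}

#' Serialize / deserialize an epoch set
#'
#' Text container standing in for an HDF5 layout: `<prefix>_data.csv` holds
#' the voltage matrix with one row per (epoch, channel) pair and one column
#' per sample; `<prefix>_meta.json` holds the time axis, labels, retention
#' flags and attributes; `<prefix>_labels.csv` is a small interoperability
#' sidecar (epoch, label, retained).
#'
#' @param epochs an `epoch_set`.
#' @param prefix path prefix for the three files.
#' @return `write_epoch_set` returns `prefix` invisibly; `read_epoch_set`
#'   returns the `epoch_set`.
#' @export
write_epoch_set <- function(epochs, prefix) {
  d <- dim(epochs$data)
  # row order: epoch-major, channel cycling within epoch
  flat <- t(matrix(epochs$data, nrow = d[1]))
  df <- data.frame(epoch = rep(seq_len(d[3]), each = d[2]),
                   channel = rep(epochs$channels, d[3]))
  df <- cbind(df, as.data.frame(flat))
  write.csv(df, paste0(prefix, "_data.csv"), row.names = FALSE)
  meta <- list(fs = epochs$fs, condition = epochs$condition,
               participant_id = epochs$participant_id,
               time = epochs$time, channels = epochs$channels,
               labels = epochs$labels, retained = epochs$retained,
               provenance = epochs$provenance)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(epoch = seq_len(d[3]), label = epochs$labels,
                       retained = epochs$retained),
            paste0(prefix, "_labels.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"))
  df <- read.csv(paste0(prefix, "_data.csv"), stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  n_ch <- length(meta$channels)
  n_ep <- nrow(df) / n_ch
  arr <- array(t(vals), dim = c(length(meta$time), n_ch, n_ep))
  epoch_set(arr, meta$time, meta$channels, meta$labels, meta$fs,
            condition = meta$condition, participant_id = meta$participant_id,
            retained = meta$retained,
            provenance = as.character(meta$provenance))
}
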