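#' Standard 34-channel 10-20 montage
#'
#' Channel names and approximate 2-D scalp positions (head radius 1, x grows
#' to the right, y to the front) for the 34-electrode arrangement used
#' throughout the package: Fp1/2, F3/4, F7/8, Fz, FC1/2, FC5/6, FT9/10, C3/4,
#' T7/8, Cz, CP1/2, CP5/6, TP9/10, P3/4, P7/8, Pz, O1/2, Iz, PO9/10.
#' Positions are only used to build smooth spatial weighting and correlation
#' kernels, so planar approximations of the 10-20 coordinates suffice.
#'
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' m <- standard_montage()
#' nrow(m) # 34
standard_montage <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
                "FC1", "FC2", "FC5", "FC6", "FT9", "FT10",
                "C3", "C4", "T7", "T8", "Cz",
                "CP1", "CP2", "CP5", "CP6", "TP9", "TP10",
                "P3", "P4", "P7", "P8", "Pz",
                "O1", "O2", "Iz", "PO9", "PO10"),
    x = c(-0.31, 0.31, -0.40, 0.40, -0.81, 0.81, 0.00,
          -0.22, 0.22, -0.69, 0.69, -0.92, 0.92,
          -0.50, 0.50, -1.00, 1.00, 0.00,
          -0.22, 0.22, -0.69, 0.69, -0.92, 0.92,
          -0.40, 0.40, -0.81, 0.81, 0.00,
          -0.31, 0.31, 0.00, -0.55, 0.55),
    y = c(0.95, 0.95, 0.55, 0.55, 0.59, 0.59, 0.50,
          0.27, 0.27, 0.28, 0.28, 0.33, 0.33,
          0.00, 0.00, 0.00, 0.00, 0.00,
          -0.27, -0.27, -0.28, -0.28, -0.33, -0.33,
          -0.55, -0.55, -0.59, -0.59, -0.50,
          -0.95, -0.95, -1.08, -0.90, -0.90),
    stringsAsFactors = FALSE
  )
}

#' Default frontocentral region of interest
#'
#' The four frontocentral electrodes over which the omission response is
#' maximal and whose unweighted mean forms the oN1 measurement channel.
#'
#' @return Character vector of channel names.
#' @export
frontocentral_roi <- function() c("Fz", "FC1", "FC2", "Cz")

#' Frontocentral oN1 scalp topography
#'
#' Smooth Gaussian weighting centred just anterior to Cz, normalized so that
#' the mean weight over the frontocentral ROI equals 1. With that
#' normalization the ROI-mean waveform of a noiseless epoch recovers the
#' configured component amplitude exactly.
#'
#' @param montage montage data.frame as from [standard_montage()].
#' @param center length-2 numeric, topography centre in montage coordinates.
#' @param sigma Gaussian width in montage units.
#' @param roi channels whose mean weight is normalized to 1.
#' @return Named numeric vector of weights, one per channel.
#' @export
on1_topography <- function(montage = standard_montage(),
                           center = c(0, 0.25), sigma = 0.45,
                           roi = frontocentral_roi()) {
  d2 <- (montage$x - center[1])^2 + (montage$y - center[2])^2
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- montage$channel
  if (!all(roi %in% montage$channel))
    stop("ROI channels missing from montage: ",
         paste(setdiff(roi, montage$channel), collapse = ", "))
  w / mean(w[roi])
}

#' Spatial correlation matrix for background noise
#'
#' Squared-exponential correlation over electrode distance. Spatially
#' independent channel noise would make multichannel decoding unrealistically
#' easy, so background noise is mixed across channels with this kernel.
#'
#' @param montage montage data.frame.
#' @param corr_length correlation length in montage (head-radius) units.
#' @return channels x channels correlation matrix (unit diagonal).
#' @export
noise_spatial_correlation <- function(montage = standard_montage(),
                                      corr_length = 0.35) {
  stopifnot(corr_length > 0)
  d2 <- outer(montage$x, montage$x, "-")^2 + outer(montage$y, montage$y, "-")^2
  K <- exp(-d2 / (2 * corr_length^2))
  dimnames(K) <- list(montage$channel, montage$channel)
  # tiny nugget keeps the Cholesky factorization well conditioned
  K + diag(1e-8, nrow(K))
}
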