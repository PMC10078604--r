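# Background-noise SNR estimation for magnitude MR images.

#' SNR from mean signal and background noise SD
#'
#' In a magnitude image the signal-free background follows a Rayleigh
#' distribution whose standard deviation is \eqn{\sqrt{2 - \pi/2}\,\sigma_g}
#' in terms of the underlying per-channel Gaussian noise \eqn{\sigma_g}.
#' Dividing the mean signal \eqn{\eta} by the background SD therefore
#' overestimates \eqn{\eta/\sigma_g}; multiplying by the correction constant
#' recovers it:
#' \deqn{\mathrm{SNR} = \sqrt{2 - \pi/2}\;\frac{\eta}{\sigma_{noise}}
#'       \approx 0.655\,\frac{\eta}{\sigma_{noise}}.}
#'
#' @param signal_mean Mean signal \eqn{\eta} over the signal ROI (>= 0).
#' @param noise_sd Standard deviation of magnitude values in a background
#'   (signal-free) region (> 0).
#' @return SNR (dimensionless, >= 0).
#' @export
#' @examples
#' estimate_snr(100, 6.5514)  # = 10.0
estimate_snr <- function(signal_mean, noise_sd) {
  stopifnot(is.numeric(signal_mean), is.numeric(noise_sd))
  if (any(noise_sd <= 0)) stop("`noise_sd` must be > 0", call. = FALSE)
  if (any(signal_mean < 0)) stop("`signal_mean` must be >= 0", call. = FALSE)
  sqrt(2 - pi / 2) * signal_mean / noise_sd
}

#' Measure SNR from signal and noise ROIs of a magnitude image
#'
#' Records the mean signal over a signal mask and the standard deviation
#' (\eqn{n-1} denominator) over a background mask outside the sample, then
#' applies [estimate_snr()]. Meant for raw (pre-denoising) images, where
#' the background is still Rayleigh-distributed.
#'
#' @param image Numeric array (2D/3D volume).
#' @param signal_mask,noise_mask Logical or 0/1 arrays on the same grid,
#'   non-empty and disjoint.
#' @param roi_label Label stored with the measurement.
#' @return An object of class `snr_measurement`: list with `signal_mean`,
#'   `noise_sd`, `snr`, `n_signal`, `n_noise`, `roi_label`.
#' @export
measure_rois <- function(image, signal_mask, noise_mask, roi_label = "ROI") {
  stopifnot(is.numeric(image))
  signal_mask <- as.logical(signal_mask)
  noise_mask <- as.logical(noise_mask)
  if (length(signal_mask) != length(image) ||
      length(noise_mask) != length(image))
    stop("masks must be on the same grid as the image", call. = FALSE)
  if (!any(signal_mask) || !any(noise_mask))
    stop("signal and noise masks must both be non-empty", call. = FALSE)
  if (any(signal_mask & noise_mask))
    stop("signal and noise masks overlap", call. = FALSE)
  eta <- mean(image[signal_mask])
  sigma <- stats::sd(image[noise_mask])
  if (!is.finite(sigma) || sigma <= 0)
    stop("background noise SD is zero; is the noise mask outside the sample?",
         call. = FALSE)
  structure(list(signal_mean = eta, noise_sd = sigma,
                 snr = estimate_snr(eta, sigma),
                 n_signal = sum(signal_mask), n_noise = sum(noise_mask),
                 roi_label = as.character(roi_label)),
            class = "snr_measurement")
}

#' @export
print.snr_measurement <- function(x, ...) {
  cat(sprintf(
    "SNR '%s': eta = %.3f over %d voxels, sigma_noise = %.3f over %d -> SNR = %.2f\n",
    x$roi_label, x$signal_mean, x$n_signal, x$noise_sd, x$n_noise, x$snr))
  invisible(x)
}
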