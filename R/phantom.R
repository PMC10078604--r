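# Synthetic phantom generation: relaxometry image series with Rician noise
# and cohort tables with Gaussian time-domain noise. Every generator is a
# deterministic function of its spec and seed.

#' Phantom specification
#'
#' Describes a labelled 3D phantom with per-region relaxation truth, used to
#' synthesize relaxometry acquisitions. The default geometry is a 32x32x4
#' volume split into three equal slabs labelled CC, cortex and thalamus,
#' with T1/T2 truths resembling gadolinium-free fixed rat brain tissue.
#'
#' @param shape Integer vector of voxel dimensions (default `c(32, 32, 4)`).
#' @param regions Integer array of region labels on that grid (0 = outside,
#'   i.e. background with zero signal). Defaults to three x-slabs 1..3.
#' @param truth Data frame with columns `region` (label index), `name`,
#'   `t1`, `t2` (ms) and `s0` (signal units).
#' @param noise_sigma Per-channel Gaussian noise SD in signal units; the
#'   magnitude image then carries Rician noise. 0 means noiseless.
#' @param seed Integer seed; mandatory whenever `noise_sigma > 0`.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(noise_sigma = 10, seed = 1)
phantom_spec <- function(shape = c(32L, 32L, 4L), regions = NULL,
                         truth = NULL, noise_sigma = 0, seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) >= 2L, all(shape >= 1L))
  if (is.null(regions)) {
    regions <- array(0L, dim = shape)
    breaks <- round(seq(0, shape[1L], length.out = 4L))
    for (r in 1:3)
      regions[(breaks[r] + 1L):breaks[r + 1L], , ] <- r
  }
  if (!identical(as.integer(dim(regions)), shape))
    stop("`regions` must have dimensions `shape`", call. = FALSE)
  if (is.null(truth)) {
    truth <- data.frame(region = 1:3,
                        name = c("CC", "cortex", "thalamus"),
                        t1 = c(876, 896, 870),
                        t2 = c(45.0, 46.8, 40.9),
                        s0 = 1000,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("region", "t1", "t2", "s0") %in% names(truth)))
  if (any(truth$t1 <= 0) || any(truth$t2 <= 0) || any(truth$s0 <= 0))
    stop("per-region truths must be positive", call. = FALSE)
  labs <- setdiff(unique(as.integer(regions)), 0L)
  if (!all(labs %in% truth$region))
    stop("every non-zero region label needs a truth row", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (noise_sigma > 0 && is.null(seed))
    stop("`seed` is mandatory for noisy phantoms", call. = FALSE)
  structure(list(shape = shape, regions = regions, truth = truth,
                 noise_sigma = noise_sigma,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phantom_spec")
}

#' Region mask of a phantom
#'
#' @param spec A [phantom_spec()].
#' @param region Region label index or name.
#' @return Logical array marking the region's voxels.
#' @export
phantom_mask <- function(spec, region) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.character(region)) {
    i <- match(region, spec$truth$name)
    if (is.na(i)) stop("unknown region name: ", region, call. = FALSE)
    region <- spec$truth$region[i]
  }
  spec$regions == as.integer(region)
}

# Rician noise: magnitude of a complex Gaussian channel pair around the
# noiseless signal. sigma = 0 returns the signal untouched.
.rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Synthesize a relaxometry acquisition series from a phantom
#'
#' Builds, per voxel, the forward model signal at each control value --
#' multi-echo decay \eqn{S_0 e^{-TE/T_2}} or saturation recovery
#' \eqn{S_0(1 - e^{-TR/T_1})} -- and adds Rician noise as the magnitude of a
#' complex Gaussian with per-channel SD `noise_sigma`. Background (region 0)
#' voxels have zero true signal, hence Rayleigh-distributed noise.
#'
#' The default control lists match common ex vivo mapping protocols:
#' 22 echoes from 8 to 176 ms in 8 ms steps for `multi_echo`, and
#' TR = 200, 400, 800, 1500, 3000, 5500 ms for `variable_tr`.
#'
#' @param spec A [phantom_spec()].
#' @param kind `"multi_echo"` or `"variable_tr"`.
#' @param control_values Positive increasing ms values; defaults as above.
#' @return An [acquisition_series()] carrying the phantom's spatial
#'   dimensions.
#' @export
#' @examples
#' s <- make_relaxometry_series(phantom_spec(), kind = "multi_echo")
make_relaxometry_series <- function(spec,
                                    kind = c("multi_echo", "variable_tr"),
                                    control_values = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(control_values))
    control_values <- if (kind == "multi_echo") seq(8, 176, by = 8)
                      else c(200, 400, 800, 1500, 3000, 5500)
  if (any(control_values <= 0) || any(diff(control_values) <= 0))
    stop("`control_values` must be positive and increasing", call. = FALSE)
  nvox <- prod(spec$shape)
  lab <- as.integer(spec$regions)
  idx <- match(lab, spec$truth$region)  # NA for background
  s0 <- ifelse(is.na(idx), 0, spec$truth$s0[idx])
  tval <- if (kind == "multi_echo") ifelse(is.na(idx), 1, spec$truth$t2[idx])
          else ifelse(is.na(idx), 1, spec$truth$t1[idx])
  if (!is.null(spec$seed)) set.seed(spec$seed)
  signals <- matrix(0, nrow = nvox, ncol = length(control_values))
  for (k in seq_along(control_values)) {
    clean <- if (kind == "multi_echo") s0 * exp(-control_values[k] / tval)
             else s0 * (1 - exp(-control_values[k] / tval))
    signals[, k] <- .rician(clean, spec$noise_sigma)
  }
  images <- array(signals, dim = c(spec$shape, length(control_values)))
  acquisition_series(images, control_values, kind)
}

#' Synthesize a relaxivity cohort table
#'
#' Generates per-sample T1 and T2 measurements at a list of contrast-agent
#' concentrations from a pair of relaxivity truths via [relaxation_time()],
#' adding Gaussian noise in the time domain (noise acts on the fitted
#' relaxation times, which is what a cohort table records, rather than on
#' raw signals). The default concentration list `{0, 15, 25, 35, 50}` mM
#' mirrors a typical perfusion-fixation design.
#'
#' @param truth_t1,truth_t2 [relaxivity_params()] truths for the two arms
#'   (`truth_t2` may be `NULL` to generate only T1 rows).
#' @param ca_list Concentrations in mM (non-empty).
#' @param n_per_ca Samples per concentration (>= 1), default 2.
#' @param noise_sd Gaussian noise SD in ms (applied per arm), default 0.
#' @param seed Integer seed, mandatory when `noise_sd > 0`.
#' @return A [cohort_table()] with `covariate` = concentration (mM).
#' @export
#' @examples
#' tr1 <- relaxivity_params(876, 0.109, "T1", tissue = "CC")
#' tr2 <- relaxivity_params(45, 0.444, "T2", tissue = "CC")
#' make_relaxivity_cohort(tr1, tr2, noise_sd = 50, seed = 7)
make_relaxivity_cohort <- function(truth_t1, truth_t2 = NULL,
                                   ca_list = c(0, 15, 25, 35, 50),
                                   n_per_ca = 2L, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth_t1, "relaxivity_params"))
  if (!length(ca_list)) stop("`ca_list` must be non-empty", call. = FALSE)
  if (n_per_ca < 1L) stop("`n_per_ca` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` is mandatory for noisy cohorts", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ca <- rep(ca_list, each = n_per_ca)
  gen_arm <- function(truth) {
    tt <- relaxation_time(truth, ca)
    if (noise_sd > 0) {
      tt <- tt + stats::rnorm(length(tt), 0, noise_sd)
      tt <- pmax(tt, 1e-6)  # relaxation times stay positive
    }
    tt
  }
  sample_id <- paste0("s", seq_along(ca))
  dfs <- list(data.frame(sample = sample_id, covariate = ca,
                         tissue = truth_t1$tissue, which = truth_t1$which,
                         time_ms = gen_arm(truth_t1),
                         stringsAsFactors = FALSE))
  if (!is.null(truth_t2)) {
    stopifnot(inherits(truth_t2, "relaxivity_params"))
    dfs[[2L]] <- data.frame(sample = sample_id, covariate = ca,
                            tissue = truth_t2$tissue, which = truth_t2$which,
                            time_ms = gen_arm(truth_t2),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, dfs)
  cohort_table(df$sample, df$covariate, df$time_ms, df$tissue, df$which)
}

#' Synthesize a rehydration time series
#'
#' Generates T2 measurements over rehydration days from an exponential
#' recovery truth \eqn{T(t) = a - b e^{-t/\tau}} plus Gaussian noise. The
#' default day schedule `{0, 2, 4, 6, 14, 24, 35}` reflects sequential
#' scanning of a soaking sample over five weeks.
#'
#' @param truth A [fit_rehydration()] result or any list with `plateau`,
#'   `amplitude`, `time_constant`.
#' @param days Non-negative increasing day list.
#' @param noise_sd Gaussian noise SD in ms, default 0.
#' @param seed Integer seed, mandatory when `noise_sd > 0`.
#' @param tissue Tissue label for the table.
#' @return A [cohort_table()] with `covariate` = days and `which = "T2"`.
#' @export
#' @examples
#' tr <- list(plateau = 60, amplitude = 30, time_constant = 7)
#' make_rehydration_series(tr, noise_sd = 1.5, seed = 11)
make_rehydration_series <- function(truth, days = c(0, 2, 4, 6, 14, 24, 35),
                                    noise_sd = 0, seed = NULL,
                                    tissue = "custom") {
  stopifnot(all(c("plateau", "amplitude", "time_constant") %in% names(truth)))
  if (any(days < 0) || any(diff(days) <= 0))
    stop("`days` must be non-negative and increasing", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` is mandatory for noisy series", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tt <- truth$plateau - truth$amplitude * exp(-days / truth$time_constant)
  if (noise_sd > 0) tt <- pmax(tt + stats::rnorm(length(tt), 0, noise_sd), 1e-6)
  cohort_table(paste0("d", seq_along(days)), days, tt, tissue, "T2")
}
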