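# Cohort-level models: contrast-agent relaxivity across concentrations and
# exponential T2 recovery across rehydration days.

#' Cohort table of per-sample relaxation times
#'
#' A tidy table with one row per sample measurement: a covariate (either the
#' contrast-agent concentration in mM, or the rehydration day), the tissue
#' label, which relaxation time was measured, and its value in ms.
#'
#' @param sample Sample identifiers.
#' @param covariate Concentration (mM) or rehydration time (days), >= 0.
#' @param time_ms Measured relaxation times in ms, > 0.
#' @param tissue Tissue label(s).
#' @param which `"T1"` or `"T2"` per row.
#' @return A `data.frame` with class `cohort_table` and columns
#'   `sample`, `covariate`, `tissue`, `which`, `time_ms`.
#' @seealso [fit_relaxivity()], [fit_rehydration()], [read_cohort_csv()]
#' @export
cohort_table <- function(sample, covariate, time_ms, tissue = "custom",
                         which = "T2") {
  df <- data.frame(sample = as.character(sample),
                   covariate = as.numeric(covariate),
                   tissue = as.character(tissue),
                   which = as.character(which),
                   time_ms = as.numeric(time_ms),
                   stringsAsFactors = FALSE)
  if (any(df$covariate < 0)) stop("covariates must be >= 0", call. = FALSE)
  if (any(df$time_ms <= 0)) stop("relaxation times must be > 0", call. = FALSE)
  if (!all(df$which %in% c("T1", "T2")))
    stop("`which` must be 'T1' or 'T2'", call. = FALSE)
  if (length(unique(df$covariate)) < 2L)
    stop("need at least 2 distinct covariate values", call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write cohort tables as CSV
#'
#' The on-disk format is a plain CSV with header
#' `sample,covariate,tissue,which,time_ms`.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns a [cohort_table()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "covariate", "tissue", "which", "time_ms")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cohort_table(df$sample, df$covariate, df$time_ms, df$tissue, df$which)
}

#' @rdname read_cohort_csv
#' @param cohort A [cohort_table()].
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort)[, c("sample", "covariate", "tissue",
                                             "which", "time_ms")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Fit the relaxivity model to a concentration cohort
#'
#' Estimates the baseline relaxation time \eqn{T_{i0}} and relaxivity
#' \eqn{r_i} of \deqn{T_i(c) = 1/(1/T_{i0} + r_i c \cdot 10^{-3})} by
#' nonlinear least squares with residuals in the *time* domain (ms), so that
#' the reported regression standard error
#' \eqn{\sigma_i = \sqrt{SSR/(n-2)}} is in ms. Starting values come from the
#' linear regression of the relaxation rate \eqn{1/T} on concentration,
#' which is exact in the noiseless case (see [fit_relaxivity_rate()] for
#' that cross-check utility). With exactly two points the model is inverted
#' in closed form.
#'
#' A negative fitted relaxivity (possible with noisy, nearly flat data) is
#' reported with a warning rather than clipped.
#'
#' @param cohort A [cohort_table()] whose covariate is concentration in mM,
#'   with at least 2 distinct concentrations. All rows are fitted together;
#'   filter to one tissue/arm first if the table mixes them.
#' @param which `"T1"` or `"T2"`; defaults to the table's (unique) value.
#' @return A [relaxivity_params()] object with `fit_stderr` filled in.
#' @export
#' @examples
#' ca <- c(0, 15, 25, 35, 50)
#' tt <- 1 / (1 / 876 + 0.109 * ca / 1000)
#' fit_relaxivity(cohort_table(seq_along(ca), ca, tt, which = "T1"))
fit_relaxivity <- function(cohort, which = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(which)) {
    which <- unique(cohort$which)
    if (length(which) != 1L)
      stop("cohort mixes T1 and T2 rows; pass `which` or filter first",
           call. = FALSE)
  }
  c_mm <- cohort$covariate
  tt <- cohort$time_ms
  if (length(unique(c_mm)) < 2L)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  n <- length(tt)
  tissue <- if (length(unique(cohort$tissue)) == 1L) cohort$tissue[1L]
            else "mixed"
  # rate-domain start (exact when noiseless)
  rate_fit <- stats::lm(I(1 / tt) ~ c_mm)
  t0_init <- 1 / stats::coef(rate_fit)[[1L]]
  r_init <- stats::coef(rate_fit)[[2L]] * 1e3
  if (!is.finite(t0_init) || t0_init <= 0) t0_init <- max(tt)
  if (n == 2L) {
    est <- c(t0 = t0_init, r = r_init)
    stderr <- 0
  } else {
    df <- data.frame(c_mm = c_mm, tt = tt)
    fit <- tryCatch(
      minpack.lm::nlsLM(tt ~ 1 / (1 / t0 + r * c_mm * 1e-3), data = df,
                        start = list(t0 = t0_init, r = r_init),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # zero-residual or degenerate data can trip the NLS machinery even
      # though the rate-domain solution is already exact; fall back to it
      est <- c(t0 = t0_init, r = r_init)
      pred <- 1 / (1 / est[["t0"]] + est[["r"]] * c_mm * 1e-3)
      stderr <- sqrt(sum((tt - pred)^2) / (n - 2))
    } else {
      est <- stats::coef(fit)
      stderr <- sqrt(sum(stats::resid(fit)^2) / (n - 2))
    }
  }
  if (est[["r"]] < 0)
    warning("fitted relaxivity is negative; check the cohort data")
  out <- suppressWarnings(
    relaxivity_params(baseline_time = est[["t0"]], relaxivity = est[["r"]],
                      which = which, tissue = tissue, fit_stderr = stderr))
  out
}

#' Rate-domain linear relaxivity fit (cross-check utility)
#'
#' Ordinary least squares of the relaxation rate \eqn{1/T} on concentration,
#' giving \eqn{1/T_{i0}} (intercept) and \eqn{r_i \cdot 10^{-3}} (slope).
#' Coincides exactly with [fit_relaxivity()] on noiseless data; on noisy data
#' the two differ because the residuals are weighted differently (rate vs
#' time domain).
#'
#' @inheritParams fit_relaxivity
#' @return A list with `baseline_time` (ms) and `relaxivity` (1/(mM s)).
#' @export
fit_relaxivity_rate <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  fit <- stats::lm(I(1 / time_ms) ~ covariate, data = cohort)
  list(baseline_time = 1 / stats::coef(fit)[[1L]],
       relaxivity = stats::coef(fit)[[2L]] * 1e3)
}

#' Exponential rehydration recovery fit
#'
#' Soaking fixed tissue in PBS washes out unbound fixative and the
#' transverse relaxation time recovers towards a plateau. This fits the
#' three-parameter exponential recovery
#' \deqn{T(t) = a - b\,e^{-t/\tau}}
#' to relaxation times measured over rehydration days: `plateau` \eqn{a}
#' (ms), `amplitude` \eqn{b} (ms, positive for recovery), and
#' `time_constant` \eqn{\tau} (days). The derived `t95` is the time to reach
#' 95% of the plateau (see [time_to_fraction()]).
#'
#' Fitting uses the self-starting asymptotic regression [stats::SSasymp()];
#' an essentially constant series is returned directly as `b = 0`,
#' `plateau = mean`, with `tau = Inf` (no kinetics to estimate). Monotone
#' *decreasing* data yields `b < 0` with a warning: the plateau is then
#' approached from above and t95 is undefined.
#'
#' @param cohort A [cohort_table()] whose covariate is rehydration time in
#'   days, with at least 3 distinct days.
#' @param fraction Plateau fraction used for the derived time, default 0.95.
#' @return An object of class `rehydration_fit`: list with `plateau`,
#'   `amplitude`, `time_constant`, `t95`, `stderr` (ms) and `converged`.
#' @export
#' @examples
#' d <- c(0, 2, 4, 6, 14, 24, 35)
#' fit_rehydration(cohort_table(seq_along(d), d, 60 - 30 * exp(-d / 7)))
fit_rehydration <- function(cohort, fraction = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  t_days <- cohort$covariate
  tt <- cohort$time_ms
  if (length(unique(t_days)) < 3L)
    stop("need at least 3 distinct days to fit the recovery curve",
         call. = FALSE)
  n <- length(tt)
  # constant series: nothing to estimate beyond the plateau
  if (stats::sd(tt) < 1e-12 * max(abs(tt))) {
    fit <- structure(list(plateau = mean(tt), amplitude = 0,
                          time_constant = Inf, stderr = 0, converged = TRUE),
                     class = "rehydration_fit")
    fit$t95 <- time_to_fraction(fit, fraction)
    return(fit)
  }
  df <- data.frame(t = t_days, y = tt)
  fit <- tryCatch(
    stats::nls(y ~ SSasymp(t, Asym, R0, lrc), data = df,
               control = stats::nls.control(maxiter = 200, tol = 1e-9,
                                            minFactor = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # SSasymp struggles on exactly noiseless data; retry with explicit
    # Levenberg-Marquardt from crude moment-style starts
    a0 <- if (tt[which.max(t_days)] >= tt[which.min(t_days)]) max(tt) * 1.05
          else min(tt) * 0.95
    b0 <- a0 - tt[which.min(t_days)]
    tau0 <- max(diff(range(t_days)) / 3, 1e-3)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a - b * exp(-t / tau), data = df,
                        start = list(a = a0, b = b0, tau = tau0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) {
      out <- structure(list(plateau = NA_real_, amplitude = NA_real_,
                            time_constant = NA_real_, t95 = NA_real_,
                            stderr = NA_real_, converged = FALSE),
                       class = "rehydration_fit")
      warning("rehydration fit did not converge")
      return(out)
    }
    cf <- stats::coef(fit)
    a <- cf[["a"]]; b <- cf[["b"]]; tau <- cf[["tau"]]
  } else {
    cf <- stats::coef(fit)
    a <- cf[["Asym"]]; b <- cf[["Asym"]] - cf[["R0"]]; tau <- exp(-cf[["lrc"]])
  }
  stderr <- sqrt(sum(stats::resid(fit)^2) / max(n - 3, 1))
  if (b < 0)
    warning("fitted amplitude is negative: series is decreasing, not recovering")
  out <- structure(list(plateau = a, amplitude = b, time_constant = tau,
                        t95 = NA_real_, stderr = stderr, converged = TRUE),
                   class = "rehydration_fit")
  out$t95 <- if (b >= 0 && a > 0) time_to_fraction(out, fraction) else NA_real_
  out
}

#' @export
print.rehydration_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Rehydration fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Rehydration fit: T(t) = %.2f - %.2f exp(-t/%.2f)  [ms, days]\n",
    x$plateau, x$amplitude, x$time_constant))
  cat(sprintf("  t95 = %.2f days, residual SE = %.3f ms\n", x$t95, x$stderr))
  invisible(x)
}

#' Time for the recovery curve to reach a fraction of its plateau
#'
#' Smallest \eqn{t \ge 0} with \eqn{a - b e^{-t/\tau} \ge f\,a}. When the
#' curve starts below the threshold (\eqn{b > (1-f)a}) this is the closed
#' form \eqn{t = \tau \log\left(b / ((1-f)a)\right)}; otherwise the curve is
#' already above it and the answer is 0 days.
#'
#' @param fit A [fit_rehydration()] result (or any list with `plateau`,
#'   `amplitude`, `time_constant`).
#' @param fraction Plateau fraction in (0, 1), default 0.95.
#' @return Time in days.
#' @export
#' @examples
#' f <- structure(list(plateau = 60, amplitude = 30, time_constant = 7),
#'                class = "rehydration_fit")
#' time_to_fraction(f)  # 7 * log(10) = 16.12 days
time_to_fraction <- function(fit, fraction = 0.95) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L)
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  a <- fit$plateau; b <- fit$amplitude; tau <- fit$time_constant
  if (!is.finite(a) || a <= 0)
    stop("plateau must be positive", call. = FALSE)
  if (b < 0)
    stop("amplitude < 0: no recovery, time to plateau fraction is undefined",
         call. = FALSE)
  if (b <= (1 - fraction) * a) return(0)
  tau * log(b / ((1 - fraction) * a))
}
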