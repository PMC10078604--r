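# Closed-form relaxivity and spin-echo signal models.
#
# Unit conventions used throughout the package: times (T1, T2, TE, TR) in
# milliseconds, contrast-agent concentrations in mM, relaxivities in
# 1/(mM s). The mM.s -> mM.ms conversion happens inside relaxation_time()
# and nowhere else.

#' Relaxivity model parameters for one tissue/fixative/agent combination
#'
#' Bundles the baseline relaxation time \eqn{T_{i0}}, the relaxivity slope
#' \eqn{r_i} of the contrast agent in that tissue, and the standard error of
#' the regression used to estimate them. One object describes either the T1
#' or the T2 arm of the model; fitting both arms for the same preparation
#' yields the pair used by the protocol planner.
#'
#' @param baseline_time Baseline relaxation time \eqn{T_{i0}} in ms
#'   (tissue with no contrast agent in the perfusate), must be positive.
#' @param relaxivity Relaxivity \eqn{r_i} in 1/(mM s); the slope of the
#'   relaxation rate \eqn{1/T_i} versus concentration. A negative value is
#'   physically implausible but tolerated with a warning so that noisy fits
#'   can be inspected rather than silently clipped.
#' @param which `"T1"` or `"T2"`: which relaxation time the parameters model.
#' @param tissue Tissue label, e.g. `"CC"`, `"cortex"`, `"thalamus"`.
#' @param fixative_pct Fixative (PFA) concentration in percent.
#' @param agent Contrast agent label, e.g. `"Gd-DTPA"` or `"gadobutrol"`.
#' @param fit_stderr Standard error of the regression in ms (0 for exact or
#'   externally supplied parameters).
#' @return An object of class `relaxivity_params`.
#' @seealso [relaxation_time()], [fit_relaxivity()], [load_relaxivity_records()]
#' @export
#' @examples
#' cc <- relaxivity_params(876, 0.109, which = "T1", tissue = "CC",
#'                         fixative_pct = 2, agent = "Gd-DTPA")
#' relaxation_time(cc, ca = 15)
relaxivity_params <- function(baseline_time, relaxivity, which = c("T1", "T2"),
                              tissue = "custom", fixative_pct = NA_real_,
                              agent = "custom", fit_stderr = 0) {
  which <- match.arg(which)
  stopifnot(is.numeric(baseline_time), length(baseline_time) == 1L,
            is.numeric(relaxivity), length(relaxivity) == 1L,
            is.numeric(fit_stderr), length(fit_stderr) == 1L)
  if (!is.finite(baseline_time) || baseline_time <= 0)
    stop("`baseline_time` must be a positive number of ms", call. = FALSE)
  if (!is.finite(relaxivity))
    stop("`relaxivity` must be finite", call. = FALSE)
  if (relaxivity < 0)
    warning("negative relaxivity is physically implausible; keeping it unclipped")
  if (fit_stderr < 0)
    stop("`fit_stderr` must be >= 0", call. = FALSE)
  structure(
    list(tissue = as.character(tissue),
         fixative_pct = as.numeric(fixative_pct),
         agent = as.character(agent),
         baseline_time = baseline_time,
         relaxivity = relaxivity,
         fit_stderr = fit_stderr,
         which = which),
    class = "relaxivity_params"
  )
}

#' @export
print.relaxivity_params <- function(x, ...) {
  cat(sprintf("Relaxivity model (%s): %s, %s%% PFA, %s\n",
              x$which, x$tissue,
              ifelse(is.na(x$fixative_pct), "?", format(x$fixative_pct)),
              x$agent))
  cat(sprintf("  baseline %s0 = %.1f ms,  r = %.3f 1/(mM s),  sigma = %.2f ms\n",
              x$which, x$baseline_time, x$relaxivity, x$fit_stderr))
  invisible(x)
}

#' A (T1, T2) relaxation-time pair for a prepared tissue
#'
#' @param t1,t2 Longitudinal and transverse relaxation times in ms. Both must
#'   be positive; `t2 <= t1` is typical for tissue but deliberately not
#'   enforced, so hypothetical or limiting cases can be explored.
#' @return An object of class `tissue_relaxation`.
#' @export
#' @examples
#' tissue_relaxation(t1 = 1705, t2 = 52)  # 4% PFA, no contrast agent
tissue_relaxation <- function(t1, t2) {
  stopifnot(is.numeric(t1), length(t1) == 1L, is.numeric(t2), length(t2) == 1L)
  if (!is.finite(t1) || t1 <= 0 || !is.finite(t2) || t2 <= 0)
    stop("`t1` and `t2` must be positive times in ms", call. = FALSE)
  structure(list(t1 = t1, t2 = t2), class = "tissue_relaxation")
}

#' @export
print.tissue_relaxation <- function(x, ...) {
  cat(sprintf("Tissue relaxation: T1 = %.1f ms, T2 = %.1f ms\n", x$t1, x$t2))
  invisible(x)
}

#' Spin-echo sequence timing parameters
#'
#' @param te Echo time in ms (> 0).
#' @param tr Repetition time in ms (>= `te`).
#' @param n_volumes Number of volumes acquired (>= 1).
#' @param time_budget Optional total scan-time budget in hours.
#' @param averages Number of signal averages (>= 1).
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(te, tr, n_volumes = 1L, time_budget = NULL,
                            averages = 1L) {
  stopifnot(is.numeric(te), length(te) == 1L, is.numeric(tr), length(tr) == 1L)
  if (!is.finite(te) || te <= 0) stop("`te` must be > 0 ms", call. = FALSE)
  if (!is.finite(tr) || tr < te) stop("`tr` must be >= `te`", call. = FALSE)
  if (n_volumes < 1) stop("`n_volumes` must be >= 1", call. = FALSE)
  if (averages < 1) stop("`averages` must be >= 1", call. = FALSE)
  if (!is.null(time_budget) && (!is.numeric(time_budget) || time_budget <= 0))
    stop("`time_budget` must be a positive number of hours", call. = FALSE)
  structure(list(te = te, tr = tr, n_volumes = as.integer(n_volumes),
                 time_budget = time_budget, averages = as.integer(averages)),
            class = "sequence_params")
}

#' Tissue preparation description
#'
#' Records how a sample was prepared: fixative concentration, contrast-agent
#' concentration in the perfusate and in the rehydration solution, and the
#' number of days of rehydration (soaking in PBS).
#'
#' @param fixative_pct Fixative (PFA) concentration in percent.
#' @param perfusate_ca Contrast-agent concentration in the perfusate, mM.
#' @param rehydration_ca Contrast-agent concentration in the rehydration
#'   solution, mM.
#' @param rehydration_days Days of rehydration (>= 0).
#' @param agent Contrast agent label.
#' @return An object of class `tissue_prep`.
#' @export
tissue_prep <- function(fixative_pct, perfusate_ca = 0, rehydration_ca = 0,
                        rehydration_days = 0, agent = "Gd-DTPA") {
  if (perfusate_ca < 0 || rehydration_ca < 0)
    stop("concentrations must be >= 0 mM", call. = FALSE)
  if (rehydration_days < 0)
    stop("`rehydration_days` must be >= 0", call. = FALSE)
  structure(list(fixative_pct = fixative_pct, perfusate_ca = perfusate_ca,
                 rehydration_ca = rehydration_ca,
                 rehydration_days = rehydration_days,
                 agent = as.character(agent)),
            class = "tissue_prep")
}

#' Observed relaxation time at a given contrast-agent concentration
#'
#' Evaluates the fast-exchange relaxivity model
#' \deqn{1/T_i = 1/T_{i0} + r_i\,[CA],}
#' which says that adding a paramagnetic contrast agent increases the
#' relaxation *rate* linearly with concentration. Since `baseline_time` is in
#' ms and `relaxivity` in 1/(mM s), the relaxivity is scaled by \eqn{10^{-3}}
#' internally to work in 1/(mM ms).
#'
#' @param params A [relaxivity_params()] object.
#' @param ca Contrast-agent concentration(s) in mM, all >= 0. Vectorized.
#' @return Relaxation time(s) in ms, in `(0, baseline_time]`. `ca = 0`
#'   returns `baseline_time` exactly.
#' @export
#' @examples
#' cc_t1 <- relaxivity_params(876, 0.109, "T1")
#' relaxation_time(cc_t1, c(0, 15, 50))
relaxation_time <- function(params, ca) {
  stopifnot(inherits(params, "relaxivity_params"), is.numeric(ca))
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("`ca` must be finite and >= 0 mM", call. = FALSE)
  1 / (1 / params$baseline_time + params$relaxivity * ca * 1e-3)
}

# Unvalidated scalar/vector core used by the optimizers (hot path).
.se_signal <- function(t1, t2, te, tr, variant) {
  s <- if (variant == "full") {
    (1 - 2 * exp(-(tr - te / 2) / t1) + exp(-tr / t1)) * exp(-te / t2)
  } else {
    (1 - exp(-tr / t1)) * exp(-te / t2)
  }
  pmax(s, 0)
}

#' Relative spin-echo signal
#'
#' Steady-state magnitude signal of a 90\eqn{^\circ}-180\eqn{^\circ} spin-echo
#' sequence, as a fraction of the fully relaxed proton-density signal:
#' \deqn{S = \left(1 - 2e^{-(TR - TE/2)/T_1} + e^{-TR/T_1}\right)
#'        e^{-TE/T_2}}
#' (`variant = "full"`). The widely used approximation that drops the
#' 180\eqn{^\circ}-pulse correction term,
#' \deqn{S = \left(1 - e^{-TR/T_1}\right) e^{-TE/T_2},}
#' is available as `variant = "simple"`; the two agree closely whenever
#' \eqn{TE \ll T_1}. Proton density and coil sensitivity are deliberately
#' absent: the value is a proportionality useful for comparing protocols on
#' the same tissue, not an absolute signal prediction.
#'
#' At degenerate timings (TR close to TE with long T1) the full expression
#' can go slightly negative; such values are clamped to zero and the result
#' carries an attribute `clamped = TRUE`.
#'
#' @param tissue A [tissue_relaxation()] object.
#' @param te Echo time(s) in ms, > 0.
#' @param tr Repetition time(s) in ms, elementwise >= `te`.
#' @param variant `"full"` (default) or `"simple"`.
#' @return Relative signal in `[0, 1]`, vectorized over `te`/`tr`, with
#'   attribute `clamped` indicating whether any value was clamped at zero.
#' @export
#' @examples
#' std <- tissue_relaxation(1705, 52)
#' spin_echo_signal(std, te = 26.78, tr = 250)
spin_echo_signal <- function(tissue, te, tr, variant = c("full", "simple")) {
  variant <- match.arg(variant)
  stopifnot(inherits(tissue, "tissue_relaxation"),
            is.numeric(te), is.numeric(tr))
  n <- max(length(te), length(tr))
  te <- rep_len(te, n); tr <- rep_len(tr, n)
  if (any(!is.finite(te)) || any(te <= 0))
    stop("`te` must be finite and > 0 ms", call. = FALSE)
  if (any(!is.finite(tr)) || any(tr < te))
    stop("`tr` must be finite and >= `te`", call. = FALSE)
  raw <- if (variant == "full") {
    (1 - 2 * exp(-(tr - te / 2) / tissue$t1) + exp(-tr / tissue$t1)) *
      exp(-te / tissue$t2)
  } else {
    (1 - exp(-tr / tissue$t1)) * exp(-te / tissue$t2)
  }
  out <- pmax(raw, 0)
  attr(out, "clamped") <- any(raw < 0)
  out
}

#' Spin-echo SNR efficiency
#'
#' SNR per square root of unit scan time,
#' \deqn{\mathrm{SNR_{eff}} \propto S(TE, TR) / \sqrt{TR},}
#' where \eqn{S} is [spin_echo_signal()]. Because scan time is proportional
#' to TR (at fixed matrix and averages) and SNR grows with the square root of
#' the time spent averaging, dividing the per-excitation signal by
#' \eqn{\sqrt{TR}} ranks protocols by the SNR attainable per unit time. The
#' absolute scale is arbitrary (units 1/\eqn{\sqrt{ms}} times proton
#' density); only ratios between parameter combinations are meaningful.
#'
#' @inheritParams spin_echo_signal
#' @return Efficiency value(s) >= 0, with the same `clamped` attribute as the
#'   underlying signal.
#' @export
#' @examples
#' opt <- tissue_relaxation(360.2, 34.6)  # 2% PFA + 15 mM Gd-DTPA
#' snr_efficiency(opt, te = 26.78, tr = 250)
snr_efficiency <- function(tissue, te, tr, variant = c("full", "simple")) {
  variant <- match.arg(variant)
  s <- spin_echo_signal(tissue, te, tr, variant)
  out <- as.numeric(s) / sqrt(rep_len(tr, length(s)))
  attr(out, "clamped") <- attr(s, "clamped")
  out
}
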