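# Protocol planning: SNR-efficiency optimization over TR and contrast-agent
# concentration, matched-TR between preparations, SNR and scan-time scaling.
#
# All optimizers are deterministic: a coarse grid locates the bracket and
# golden-section (stats::optimize) or bisection (stats::uniroot) refines it.

# Efficiency as a function of concentration for a T1/T2 relaxivity pair.
.eff_of_ca <- function(p1, p2, te, tr, variant) {
  function(ca) {
    t1 <- 1 / (1 / p1$baseline_time + p1$relaxivity * ca * 1e-3)
    t2 <- 1 / (1 / p2$baseline_time + p2$relaxivity * ca * 1e-3)
    .se_signal(t1, t2, te, tr, variant) / sqrt(tr)
  }
}

#' Optimal repetition time for a given tissue and echo time
#'
#' Maximizes [snr_efficiency()] over TR. Longer TR recovers more longitudinal
#' magnetization but costs scan time, so the efficiency
#' \eqn{S(TE,TR)/\sqrt{TR}} has an interior maximum at a TR commensurate with
#' \eqn{T_1} (in the short-TE limit, at \eqn{TR/T_1 \approx 1.2564}, the root
#' of \eqn{e^x = 2x + 1}). A coarse grid locates the bracket and
#' golden-section search refines it.
#'
#' @param tissue A [tissue_relaxation()] object.
#' @param te Echo time in ms.
#' @param tr_bounds Finite search bounds in ms, `tr_bounds[1] >= te`.
#' @param variant Signal-equation variant, `"full"` or `"simple"`.
#' @param tol Refinement tolerance in ms.
#' @return A list with `tr` (ms), `efficiency` at the optimum, and
#'   `boundary` (`TRUE` when the optimum sits on a search bound).
#' @export
#' @examples
#' optimal_tr(tissue_relaxation(360, 35), te = 27)
optimal_tr <- function(tissue, te, tr_bounds = c(te, 10000),
                       variant = c("full", "simple"), tol = 1e-3) {
  variant <- match.arg(variant)
  stopifnot(inherits(tissue, "tissue_relaxation"),
            is.numeric(te), length(te) == 1L, te > 0,
            is.numeric(tr_bounds), length(tr_bounds) == 2L)
  if (any(!is.finite(tr_bounds)) || tr_bounds[1] < te ||
      tr_bounds[2] <= tr_bounds[1])
    stop("`tr_bounds` must be finite, increasing and within [te, Inf)",
         call. = FALSE)
  f <- function(tr) .se_signal(tissue$t1, tissue$t2, te, tr, variant) / sqrt(tr)
  grid <- seq(tr_bounds[1], tr_bounds[2], length.out = 201L)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  # endpoints beat the interior refinement when the surface is monotone
  cand_tr <- c(opt$maximum, tr_bounds)
  cand_v <- c(opt$objective, f(tr_bounds[1]), f(tr_bounds[2]))
  best <- which.max(cand_v)
  tr_star <- cand_tr[best]
  boundary <- best > 1L || min(abs(tr_star - tr_bounds)) <= 2 * tol
  list(tr = tr_star, efficiency = cand_v[best], boundary = boundary)
}

#' Optimal contrast-agent concentration with 95%-of-max interval
#'
#' Contrast agent shortens \eqn{T_1} (allowing short TR without saturation)
#' but also shortens \eqn{T_2} (costing signal at the echo time), so SNR
#' efficiency is unimodal in concentration for positive relaxivities. This
#' finds the concentration maximizing
#' \eqn{\mathrm{eff}(c) = S(T_1(c), T_2(c), TE, TR)/\sqrt{TR}}, where
#' \eqn{T_i(c)} follow [relaxation_time()], and brackets it with the
#' contiguous interval over which efficiency stays above
#' `threshold_fraction` of the maximum. Interval endpoints are refined by
#' bisection; an endpoint clipped at a search bound is flagged.
#'
#' Unimodality is asserted on the coarse grid; in the (unexpected) event of
#' multiple local maxima a warning is issued and the component containing
#' the argmax is returned.
#'
#' @param p1,p2 [relaxivity_params()] for the T1 and T2 arms of the same
#'   tissue/fixative/agent preparation.
#' @param te,tr Echo and repetition time in ms.
#' @param ca_bounds Concentration search bounds in mM, default `c(0, 100)`.
#' @param variant Signal-equation variant.
#' @param threshold_fraction Fraction of the maximum efficiency defining the
#'   interval, default 0.95.
#' @param tol Endpoint refinement tolerance in mM, default 0.1.
#' @return An object of class `concentration_interval`: list with `argmax`
#'   (mM), `max_efficiency`, `lo`, `hi` (mM), `threshold_fraction`,
#'   `bounded_lo`/`bounded_hi` flags, and the evaluation context
#'   (`te`, `tr`, `variant`).
#' @export
#' @examples
#' t1p <- relaxivity_params(896, 0.167, "T1", tissue = "cortex")
#' t2p <- relaxivity_params(46.8, 0.801, "T2", tissue = "cortex")
#' optimal_concentration(t1p, t2p, te = 27, tr = 250)
optimal_concentration <- function(p1, p2, te, tr, ca_bounds = c(0, 100),
                                  variant = c("full", "simple"),
                                  threshold_fraction = 0.95, tol = 0.1) {
  variant <- match.arg(variant)
  stopifnot(inherits(p1, "relaxivity_params"), inherits(p2, "relaxivity_params"))
  if (p1$which != "T1" || p2$which != "T2")
    stop("`p1` must be the T1 arm and `p2` the T2 arm", call. = FALSE)
  if (!identical(p1$tissue, p2$tissue) || !identical(p1$agent, p2$agent))
    warning("p1 and p2 describe different tissues/agents")
  if (length(ca_bounds) != 2L || any(ca_bounds < 0) ||
      ca_bounds[2] <= ca_bounds[1])
    stop("`ca_bounds` must be increasing and >= 0 mM", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  eff <- .eff_of_ca(p1, p2, te, tr, variant)
  step <- min(1, diff(ca_bounds) / 100)
  grid <- seq(ca_bounds[1], ca_bounds[2], by = step)
  vals <- eff(grid)
  # unimodality check: sign pattern of first differences must be + then -
  dv <- diff(vals)
  sgn <- sign(dv[abs(dv) > 1e-12 * max(vals)])
  if (length(sgn) && sum(diff(sgn) != 0) > 1L)
    warning("efficiency profile is not unimodal on the coarse grid; ",
            "returning the component containing the argmax")
  i <- which.max(vals)
  lo_b <- grid[max(i - 1L, 1L)]; hi_b <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(eff, c(lo_b, hi_b), maximum = TRUE, tol = tol / 100)
  cand_c <- c(opt$maximum, ca_bounds)
  cand_v <- c(opt$objective, eff(ca_bounds[1]), eff(ca_bounds[2]))
  best <- which.max(cand_v)
  argmax <- cand_c[best]; vmax <- cand_v[best]
  argmax_bounded <- best > 1L
  target <- threshold_fraction * vmax
  g <- function(ca) eff(ca) - target
  if (g(ca_bounds[1]) >= 0) {
    lo <- ca_bounds[1]; bounded_lo <- TRUE
  } else {
    lo <- stats::uniroot(g, c(ca_bounds[1], argmax), tol = tol / 10)$root
    bounded_lo <- FALSE
  }
  if (g(ca_bounds[2]) >= 0) {
    hi <- ca_bounds[2]; bounded_hi <- TRUE
  } else {
    hi <- stats::uniroot(g, c(argmax, ca_bounds[2]), tol = tol / 10)$root
    bounded_hi <- FALSE
  }
  structure(list(argmax = argmax, max_efficiency = vmax, lo = lo, hi = hi,
                 threshold_fraction = threshold_fraction,
                 bounded_lo = bounded_lo, bounded_hi = bounded_hi,
                 argmax_at_bound = argmax_bounded,
                 te = te, tr = tr, variant = variant),
            class = "concentration_interval")
}

#' @export
print.concentration_interval <- function(x, ...) {
  cat(sprintf(
    "Optimal [CA] at TE = %g ms, TR = %g ms (%s variant):\n",
    x$te, x$tr, x$variant))
  cat(sprintf("  argmax = %.1f mM (efficiency %.3g)%s\n", x$argmax,
              x$max_efficiency, if (x$argmax_at_bound) " [at bound]" else ""))
  cat(sprintf("  %.0f%%-of-max interval: [%.1f, %.1f] mM%s%s\n",
              100 * x$threshold_fraction, x$lo, x$hi,
              if (x$bounded_lo) " [lo clipped]" else "",
              if (x$bounded_hi) " [hi clipped]" else ""))
  invisible(x)
}

#' SNR-efficiency surface over TE, TR and concentration grids
#'
#' Dense evaluation of the concentration-resolved SNR efficiency for every
#' grid combination, plus the per-(TE, TR) concentration maximizing it.
#' Cells with `tr < te` are invalid for a spin echo and masked with `NA`.
#'
#' @inheritParams optimal_concentration
#' @param te_grid,tr_grid,ca_grid Non-empty increasing grids (ms, ms, mM).
#' @return An object of class `efficiency_surface`: list with `values`
#'   (array `[te, tr, ca]`), `opt_ca` and `opt_value` (matrices `[te, tr]`),
#'   the grids, the `variant`, and `optimum` (list `te`, `tr`, `ca`,
#'   `value` at the global grid maximum).
#' @export
efficiency_surface <- function(p1, p2, te_grid, tr_grid, ca_grid,
                               variant = c("full", "simple")) {
  variant <- match.arg(variant)
  stopifnot(length(te_grid) >= 1L, length(tr_grid) >= 1L,
            length(ca_grid) >= 1L,
            all(te_grid > 0), all(tr_grid > 0), all(ca_grid >= 0))
  t1 <- relaxation_time(p1, ca_grid)
  t2 <- relaxation_time(p2, ca_grid)
  vals <- array(NA_real_,
                dim = c(length(te_grid), length(tr_grid), length(ca_grid)))
  for (i in seq_along(te_grid)) {
    for (j in seq_along(tr_grid)) {
      if (tr_grid[j] < te_grid[i]) next
      vals[i, j, ] <- .se_signal(t1, t2, te_grid[i], tr_grid[j], variant) /
        sqrt(tr_grid[j])
    }
  }
  if (all(is.na(vals)))
    stop("all grid cells have tr < te: nothing to evaluate", call. = FALSE)
  opt_ca <- opt_value <- matrix(NA_real_, length(te_grid), length(tr_grid))
  for (i in seq_along(te_grid)) {
    for (j in seq_along(tr_grid)) {
      v <- vals[i, j, ]
      if (all(is.na(v))) next
      k <- which.max(v)
      opt_ca[i, j] <- ca_grid[k]
      opt_value[i, j] <- v[k]
    }
  }
  k_best <- which(opt_value == max(opt_value, na.rm = TRUE),
                  arr.ind = TRUE)[1L, ]
  optimum <- list(te = te_grid[k_best[1L]], tr = tr_grid[k_best[2L]],
                  ca = opt_ca[k_best[1L], k_best[2L]],
                  value = opt_value[k_best[1L], k_best[2L]])
  structure(list(values = vals, opt_ca = opt_ca, opt_value = opt_value,
                 te_grid = te_grid, tr_grid = tr_grid, ca_grid = ca_grid,
                 variant = variant, optimum = optimum),
            class = "efficiency_surface")
}

#' @export
print.efficiency_surface <- function(x, ...) {
  cat(sprintf("SNR-efficiency surface (%s): %d TE x %d TR x %d [CA] cells\n",
              x$variant, length(x$te_grid), length(x$tr_grid),
              length(x$ca_grid)))
  cat(sprintf("  optimum: TE = %g ms, TR = %g ms, [CA] = %g mM (%.3g)\n",
              x$optimum$te, x$optimum$tr, x$optimum$ca, x$optimum$value))
  invisible(x)
}

#' @export
as.data.frame.efficiency_surface <- function(x, ...) {
  g <- expand.grid(te = x$te_grid, tr = x$tr_grid, ca = x$ca_grid,
                   KEEP.OUT.ATTRS = FALSE)
  g$efficiency <- as.vector(x$values)
  g
}

#' Repetition time matching a reference per-excitation signal
#'
#' Finds the TR at which a target tissue produces the same per-excitation
#' spin-echo signal as a reference tissue does at its own (TE, TR). This is
#' the tool for asking "how long would TR need to be for the un-optimized
#' preparation to match the optimized one's signal?". Solved by bisection;
#' the result plugged back into [spin_echo_signal()] reproduces the
#' reference signal to better than 1e-6 relative.
#'
#' The target's attainable signal at fixed TE saturates at
#' \eqn{e^{-TE/T_2}}; if that asymptote is below the reference signal no TR
#' can match it and an error reports the asymptote.
#'
#' @param reference [tissue_relaxation()] of the reference preparation.
#' @param seq [sequence_params()] giving the shared TE and the reference TR.
#' @param target [tissue_relaxation()] of the preparation whose TR is sought.
#' @param variant Signal-equation variant.
#' @return Matching TR in ms.
#' @export
#' @examples
#' opt <- tissue_relaxation(360.2, 34.6)
#' std <- tissue_relaxation(1705, 52)
#' matched_tr(opt, sequence_params(te = 26.78, tr = 250), std)
matched_tr <- function(reference, seq, target, variant = c("full", "simple")) {
  variant <- match.arg(variant)
  stopifnot(inherits(reference, "tissue_relaxation"),
            inherits(seq, "sequence_params"),
            inherits(target, "tissue_relaxation"))
  te <- seq$te
  s_ref <- .se_signal(reference$t1, reference$t2, te, seq$tr, variant)
  asymptote <- exp(-te / target$t2)
  if (asymptote <= s_ref)
    stop(sprintf(paste0("target cannot reach the reference signal %.4g: ",
                        "its TE-fixed asymptote is %.4g"), s_ref, asymptote),
         call. = FALSE)
  f <- function(tr) .se_signal(target$t1, target$t2, te, tr, variant) - s_ref
  if (f(te) >= 0) return(te)  # target matches already at the minimum TR
  hi <- max(seq$tr, 10 * target$t1)
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  stats::uniroot(f, c(te, hi), tol = 1e-9)$root
}

#' Predict SNR of one preparation from another's measurement
#'
#' Scales a measured SNR by the ratio of per-excitation spin-echo signals
#' between a target and a reference tissue at the same TE and TR, optionally
#' scaled by \eqn{\sqrt{N}} for a change in the number of signal averages.
#' Because proton-density differences are ignored, this is meaningful for
#' the same tissue under different preparations (different \eqn{T_1},
#' \eqn{T_2}), not across tissue types.
#'
#' @param measured_snr SNR measured on the reference preparation (> 0).
#' @param reference,target [tissue_relaxation()] objects.
#' @param seq [sequence_params()] with the shared TE and TR.
#' @param variant Signal-equation variant.
#' @param averages_ratio Ratio of signal averages (target / reference);
#'   SNR scales with its square root.
#' @return Predicted SNR (dimensionless).
#' @export
#' @examples
#' opt <- tissue_relaxation(360.2, 34.6); std <- tissue_relaxation(1705, 52)
#' predict_snr(12, opt, std, sequence_params(26.78, 250))
predict_snr <- function(measured_snr, reference, target, seq,
                        variant = c("full", "simple"), averages_ratio = 1) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(measured_snr), length(measured_snr) == 1L,
            inherits(reference, "tissue_relaxation"),
            inherits(target, "tissue_relaxation"),
            inherits(seq, "sequence_params"))
  if (measured_snr <= 0) stop("`measured_snr` must be > 0", call. = FALSE)
  if (averages_ratio <= 0) stop("`averages_ratio` must be > 0", call. = FALSE)
  s_ref <- .se_signal(reference$t1, reference$t2, seq$te, seq$tr, variant)
  if (s_ref <= 0)
    stop("reference signal is zero at this TE/TR", call. = FALSE)
  s_tgt <- .se_signal(target$t1, target$t2, seq$te, seq$tr, variant)
  measured_snr * (s_tgt / s_ref) * sqrt(averages_ratio)
}

#' Scan-time scaling
#'
#' Total scan time is linear in both TR and the number of signal averages
#' (at fixed matrix size), so changing either rescales the time by the
#' corresponding ratio.
#'
#' @param base Scan time in hours.
#' @param tr_ratio New TR / old TR (> 0).
#' @param averages_ratio New averages / old averages (> 0).
#' @return Scaled scan time in hours.
#' @export
#' @examples
#' scale_scan_time(91.35, tr_ratio = 750 / 250)  # 274.05 h
scale_scan_time <- function(base, tr_ratio = 1, averages_ratio = 1) {
  stopifnot(is.numeric(base), base >= 0)
  if (tr_ratio <= 0 || averages_ratio <= 0)
    stop("ratios must be > 0", call. = FALSE)
  base * tr_ratio * averages_ratio
}

#' Baseline relaxation-time ratios between contrast agents
#'
#' Compares two contrast agents through the ratio of their fitted baseline
#' relaxation times (numerator agent / denominator agent) in each tissue,
#' from a table of relaxivity records such as [load_relaxivity_records()].
#' Baselines here reflect tissue rehydrated in 1 mM of the respective agent,
#' so the ratio captures how much more strongly one agent shortens
#' relaxation at matched preparation.
#'
#' @param records Data frame of relaxivity records (see
#'   [load_relaxivity_records()]).
#' @param agent_num,agent_den Agent labels for numerator and denominator.
#' @param fixative_pct Fixative concentration the comparison is restricted
#'   to (default 2).
#' @param which `"T1"` or `"T2"`.
#' @return Data frame with columns `tissue` and `ratio`.
#' @export
agent_baseline_ratios <- function(records, agent_num = "gadobutrol",
                                  agent_den = "Gd-DTPA", fixative_pct = 2,
                                  which = c("T1", "T2")) {
  which <- match.arg(which)
  col <- if (which == "T1") "T10" else "T20"
  num <- records[records$agent == agent_num &
                   records$fixative_pct == fixative_pct, ]
  den <- records[records$agent == agent_den &
                   records$fixative_pct == fixative_pct, ]
  tissues <- intersect(num$tissue, den$tissue)
  if (!length(tissues))
    stop("no shared tissues between the two agents", call. = FALSE)
  data.frame(tissue = tissues,
             ratio = num[[col]][match(tissues, num$tissue)] /
                     den[[col]][match(tissues, den$tissue)],
             stringsAsFactors = FALSE)
}

#' Plan an acquisition for a tissue preparation
#'
#' Convenience wrapper producing a plan report: the optimal contrast-agent
#' concentration (with its threshold interval) at the requested TE/TR, the
#' predicted tissue relaxation times at that concentration, and the SNR
#' efficiency achieved.
#'
#' @inheritParams optimal_concentration
#' @return An object of class `plan_report`: list with the
#'   [optimal_concentration()] interval, `tissue` (predicted
#'   [tissue_relaxation()] at the chosen concentration), `efficiency`,
#'   and the inputs.
#' @export
plan_protocol <- function(p1, p2, te, tr, ca_bounds = c(0, 100),
                          variant = c("full", "simple"),
                          threshold_fraction = 0.95) {
  variant <- match.arg(variant)
  ci <- optimal_concentration(p1, p2, te, tr, ca_bounds, variant,
                              threshold_fraction)
  tis <- tissue_relaxation(relaxation_time(p1, ci$argmax),
                           relaxation_time(p2, ci$argmax))
  structure(list(interval = ci, ca = ci$argmax, te = te, tr = tr,
                 tissue = tis, efficiency = ci$max_efficiency,
                 variant = variant,
                 params = list(t1 = p1, t2 = p2)),
            class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  cat("Acquisition plan\n")
  cat(sprintf("  tissue: %s, %s%% PFA, %s\n", x$params$t1$tissue,
              format(x$params$t1$fixative_pct), x$params$t1$agent))
  print(x$interval)
  cat(sprintf("  predicted tissue at %.1f mM: T1 = %.1f ms, T2 = %.1f ms\n",
              x$ca, x$tissue$t1, x$tissue$t2))
  invisible(x)
}
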