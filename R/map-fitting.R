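# Voxelwise and per-curve estimation of T1 (variable-TR saturation
# recovery) and T2 (multi-echo decay) from magnitude image series.

#' Acquisition series container
#'
#' Holds a stack of magnitude volumes acquired while varying one timing
#' parameter: the repetition time (variable-TR saturation recovery, for T1
#' mapping) or the echo time (multi-echo decay, for T2 mapping).
#'
#' @param images Numeric array whose last dimension indexes volumes, or a
#'   plain vector holding a single voxel's signal across volumes, or a
#'   matrix with one row per voxel and one column per volume.
#' @param control_values Strictly increasing vector of ms values (the TR or
#'   TE of each volume), one per volume.
#' @param kind `"multi_echo"` (TE list, T2 mapping) or `"variable_tr"`
#'   (TR list, T1 mapping).
#' @return An object of class `acquisition_series` with elements `signals`
#'   (voxels x volumes matrix), `dim` (spatial dimensions, NULL for bare
#'   vectors/matrices), `control_values` and `kind`.
#' @seealso [fit_t2_decay()], [fit_t1_recovery()], [fit_map()],
#'   [make_relaxometry_series()]
#' @export
acquisition_series <- function(images, control_values,
                               kind = c("multi_echo", "variable_tr")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(control_values), is.numeric(images))
  cv <- as.numeric(control_values)
  if (length(cv) < 2L || any(diff(cv) <= 0) || any(cv <= 0))
    stop("`control_values` must be >= 2 strictly increasing positive ms values",
         call. = FALSE)
  spatial_dim <- NULL
  if (is.null(dim(images))) {
    signals <- matrix(images, nrow = 1L)
  } else if (length(dim(images)) == 2L) {
    signals <- unclass(images)
  } else {
    d <- dim(images)
    spatial_dim <- d[-length(d)]
    # column-major layout: flattening keeps voxels in rows, volumes in columns
    signals <- matrix(images, nrow = prod(spatial_dim), ncol = d[length(d)])
  }
  if (ncol(signals) != length(cv))
    stop("need exactly one control value per volume", call. = FALSE)
  if (any(signals < 0))
    stop("magnitude signals must be >= 0", call. = FALSE)
  structure(list(signals = signals, dim = spatial_dim,
                 control_values = cv, kind = kind),
            class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat(sprintf("Acquisition series (%s): %d voxel(s) x %d volumes\n",
              x$kind, nrow(x$signals), ncol(x$signals)))
  cat("  control values (ms):", paste(format(x$control_values), collapse = ", "),
      "\n")
  invisible(x)
}

# Exact two-point closed forms ------------------------------------------

# T2 from two echoes: T2 = dTE / log(S1/S2); S0 back-extrapolated.
.two_point_t2 <- function(te, s) {
  if (s[2] >= s[1] || s[2] <= 0)
    return(list(s0 = NA_real_, t = NA_real_, converged = FALSE))
  t2 <- (te[2] - te[1]) / log(s[1] / s[2])
  list(s0 = s[1] * exp(te[1] / t2), t = t2, converged = TRUE)
}

# T1 from two TRs: solve S1/S2 = (1-e^{-TR1/T1})/(1-e^{-TR2/T1}) for T1.
# The ratio is strictly increasing in T1, so the root is unique.
.two_point_t1 <- function(tr, s) {
  if (s[1] >= s[2] || s[1] <= 0)
    return(list(s0 = NA_real_, t = NA_real_, converged = FALSE))
  target <- s[1] / s[2]
  f <- function(t1) (1 - exp(-tr[1] / t1)) / (1 - exp(-tr[2] / t1)) - target
  # f(t1 -> 0) = 1 - target < 0 is wrong orientation; as t1 -> 0 ratio -> 1,
  # as t1 -> Inf ratio -> tr1/tr2 < 1. target is in (tr1/tr2, 1).
  lo <- 1e-3; hi <- 1e3
  while (f(hi) > 0 && hi < 1e9) hi <- hi * 10
  if (f(lo) < 0 || f(hi) > 0)
    return(list(s0 = NA_real_, t = NA_real_, converged = FALSE))
  t1 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(s0 = s[1] / (1 - exp(-tr[1] / t1)), t = t1, converged = TRUE)
}

# Shared nonlinear fitting engine. `model` maps (s0, t, x) -> signal.
.fit_relax_curve <- function(x, s, kind, truncate_after = NULL) {
  if (!is.null(truncate_after)) {
    keep <- x <= truncate_after
    x <- x[keep]; s <- s[keep]
  }
  n <- length(x)
  if (n < 2L)
    return(list(s0 = NA_real_, t = NA_real_, stderr = NA_real_,
                converged = FALSE))
  # a decay must trend down, a recovery up; flat or inverted curves have no
  # finite relaxation time (T -> Inf or 0) and are flagged, not fitted
  trend <- sum((x - mean(x)) * (s - mean(s)))
  if ((kind == "multi_echo" && trend >= 0) ||
      (kind == "variable_tr" && trend <= 0))
    return(list(s0 = NA_real_, t = NA_real_, stderr = NA_real_,
                converged = FALSE))
  two_point <- if (kind == "multi_echo") .two_point_t2 else .two_point_t1
  if (n == 2L) {
    tp <- two_point(x, s)
    return(list(s0 = tp$s0, t = tp$t, stderr = 0, converged = tp$converged))
  }
  # Deterministic, scale-free start: relaxation time from the two
  # most-separated points' closed form, S0 from the largest signal.
  i <- c(which.min(x), which.max(x))
  tp <- two_point(x[i], s[i])
  t_init <- tp$t
  if (!tp$converged || !is.finite(t_init) || t_init <= 0)
    t_init <- diff(range(x))  # fallback bracket: order of the sampled range
  s0_init <- max(s)
  df <- data.frame(x = x, s = s)
  form <- if (kind == "multi_echo") s ~ s0 * exp(-x / t)
          else s ~ s0 * (1 - exp(-x / t))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df,
                      start = list(s0 = s0_init, t = t_init),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(s0 = NA_real_, t = NA_real_, stderr = NA_real_,
                converged = FALSE))
  est <- stats::coef(fit)
  if (!all(is.finite(est)) || est[["t"]] <= 0 || est[["s0"]] <= 0 ||
      est[["t"]] > 1e4 * max(x))   # far beyond the sampled range: T -> Inf
    return(list(s0 = NA_real_, t = NA_real_, stderr = NA_real_,
                converged = FALSE))
  ssr <- sum(stats::resid(fit)^2)
  list(s0 = unname(est[["s0"]]), t = unname(est[["t"]]),
       stderr = sqrt(ssr / (n - 2)), converged = TRUE)
}

.as_curve <- function(series, signal, kind_wanted) {
  if (inherits(series, "acquisition_series")) {
    if (series$kind != kind_wanted)
      stop(sprintf("series kind is '%s', expected '%s'", series$kind,
                   kind_wanted), call. = FALSE)
    if (nrow(series$signals) != 1L)
      stop("series holds multiple voxels; use fit_map() for voxelwise fitting",
           call. = FALSE)
    list(x = series$control_values, s = as.numeric(series$signals[1L, ]))
  } else {
    stopifnot(is.numeric(series), is.numeric(signal),
              length(series) == length(signal))
    list(x = as.numeric(series), s = as.numeric(signal))
  }
}

#' Fit a mono-exponential T2 decay
#'
#' Least-squares fit of \eqn{S(TE) = S_0 e^{-TE/T_2}} to a multi-echo decay
#' curve. With exactly two echoes the exact closed form
#' \eqn{T_2 = \Delta TE / \log(S_1/S_2)} is used. With three or more, a
#' Levenberg-Marquardt fit is initialized from the closed form of the two
#' most-separated echoes and \eqn{S_0} from the largest signal.
#'
#' Non-decaying input (e.g. constant signal, for which \eqn{T_2 \to \infty})
#' is reported as non-convergence via `converged = FALSE`, never as an
#' exception, so that voxelwise map fitting can count failures and move on.
#'
#' @param series An `acquisition_series` of kind `"multi_echo"` holding a
#'   single voxel, or a numeric vector of echo times in ms.
#' @param signal When `series` is a vector of echo times: the matching
#'   signal values.
#' @param truncate_after Optional TE cutoff in ms; echoes later than this are
#'   dropped before fitting (all echoes are used by default).
#' @return A list with `s0`, `t2` (ms), `stderr` (residual standard error,
#'   ms-domain signal units) and `converged`.
#' @export
#' @examples
#' te <- seq(8, 176, by = 8)
#' fit_t2_decay(te, 1000 * exp(-te / 35))
fit_t2_decay <- function(series, signal = NULL, truncate_after = NULL) {
  cur <- .as_curve(series, signal, "multi_echo")
  f <- .fit_relax_curve(cur$x, cur$s, "multi_echo", truncate_after)
  list(s0 = f$s0, t2 = f$t, stderr = f$stderr, converged = f$converged)
}

#' Fit a saturation-recovery T1 curve
#'
#' Least-squares fit of \eqn{S(TR) = S_0 (1 - e^{-TR/T_1})} to signals
#' acquired at increasing repetition times. With exactly two TRs the model is
#' inverted exactly (the signal ratio is strictly monotone in \eqn{T_1}).
#' With three or more points a Levenberg-Marquardt fit is used, initialized
#' as in [fit_t2_decay()].
#'
#' @param series An `acquisition_series` of kind `"variable_tr"` holding a
#'   single voxel, or a numeric vector of repetition times in ms.
#' @param signal When `series` is a vector of TRs: the matching signals.
#' @return A list with `s0`, `t1` (ms), `stderr` and `converged`.
#' @export
#' @examples
#' tr <- c(200, 400, 800, 1500, 3000, 5500)
#' fit_t1_recovery(tr, 500 * (1 - exp(-tr / 876)))
fit_t1_recovery <- function(series, signal = NULL) {
  cur <- .as_curve(series, signal, "variable_tr")
  f <- .fit_relax_curve(cur$x, cur$s, "variable_tr")
  list(s0 = f$s0, t1 = f$t, stderr = f$stderr, converged = f$converged)
}

#' Voxelwise relaxometry map fitting
#'
#' Applies [fit_t2_decay()] or [fit_t1_recovery()] (chosen by the series
#' kind) independently to every voxel of an acquisition series. Fitting is
#' geometry-agnostic: each voxel's curve is fitted on its own, and the
#' spatial shape of the input is restored on output. Voxels whose fit does
#' not converge carry the sentinel `NA` in both maps and are counted in
#' `n_nonconverged`; they are excluded, not imputed.
#'
#' @param series An [acquisition_series()] (any number of voxels).
#' @param truncate_after Optional TE cutoff forwarded to the T2 fitter.
#' @return An object of class `parameter_map`: list with `values` (fitted
#'   relaxation time, ms), `s0` (fitted equilibrium signal), `quality`
#'   (residual standard error per voxel), `kind` (`"T1"` or `"T2"`), and
#'   `n_nonconverged`. Arrays keep the spatial dimensions of the input.
#' @export
fit_map <- function(series, truncate_after = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  x <- series$control_values
  nv <- nrow(series$signals)
  vals <- s0s <- qual <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    f <- .fit_relax_curve(x, as.numeric(series$signals[v, ]), series$kind,
                          truncate_after)
    if (isTRUE(f$converged)) {
      vals[v] <- f$t; s0s[v] <- f$s0; qual[v] <- f$stderr
    }
  }
  if (!is.null(series$dim)) {
    dim(vals) <- series$dim; dim(s0s) <- series$dim; dim(qual) <- series$dim
  }
  structure(list(values = vals, s0 = s0s, quality = qual,
                 kind = if (series$kind == "multi_echo") "T2" else "T1",
                 n_nonconverged = sum(is.na(vals))),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("%s parameter map: %d voxel(s), %d non-converged\n",
              x$kind, length(x$values), x$n_nonconverged))
  invisible(x)
}

#' Region-of-interest statistics on a parameter map
#'
#' Mean and standard deviation (with the usual \eqn{n-1} denominator) of a
#' fitted parameter map over a binary mask. Non-converged (sentinel `NA`)
#' voxels inside the mask are excluded and counted.
#'
#' @param map A [fit_map()] result, or a bare numeric array of values.
#' @param mask Logical or 0/1 numeric array on the same grid as the map.
#' @param roi_label Label stored with the result.
#' @return An object of class `roi_stats`: list with `mean`, `sd`,
#'   `n_voxels` (converged voxels used), `n_excluded` and `roi_label`.
#' @export
#' @examples
#' m <- array(c(40, 60, 80, 100), dim = c(2, 2))
#' roi_stats(m, array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2)))
roi_stats <- function(map, mask, roi_label = "ROI") {
  values <- if (inherits(map, "parameter_map")) map$values else map
  stopifnot(is.numeric(values))
  mask <- as.logical(mask)
  if (length(mask) != length(values))
    stop("`mask` must be on the same grid as the map", call. = FALSE)
  if (!any(mask, na.rm = TRUE))
    stop("empty mask: no voxels selected", call. = FALSE)
  sel <- values[mask]
  ok <- is.finite(sel)
  if (!any(ok))
    stop("all in-mask voxels are flagged non-converged", call. = FALSE)
  structure(list(mean = mean(sel[ok]),
                 sd = if (sum(ok) > 1L) stats::sd(sel[ok]) else 0,
                 n_voxels = sum(ok),
                 n_excluded = sum(!ok),
                 roi_label = as.character(roi_label)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI '%s': mean = %.3f, sd = %.3f (n = %d, excluded = %d)\n",
              x$roi_label, x$mean, x$sd, x$n_voxels, x$n_excluded))
  invisible(x)
}
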