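test_that("optimal TR approaches the short-TE closed-form limit", {
  # at te -> 0 the efficiency S/sqrt(TR) peaks at TR/T1 = x*, e^x = 2x + 1
  xstar <- stats::uniroot(function(x) exp(x) - 2 * x - 1, c(0.5, 3),
                          tol = 1e-12)$root
  for (t1 in c(400, 876, 1705)) {
    tis <- tissue_relaxation(t1, 1e6)
    opt <- optimal_tr(tis, te = 1e-6, tr_bounds = c(1e-6, 10 * t1),
                      variant = "simple")
    expect_equal(opt$tr / t1, xstar, tolerance = 1e-3)
    expect_false(opt$boundary)
  }
})

test_that("optimal TR matches an exhaustive 0.1 ms grid search", {
  tis <- tissue_relaxation(360, 35)
  opt <- optimal_tr(tis, te = 27, tr_bounds = c(27, 3000))
  grid <- seq(27, 3000, by = 0.1)
  brute <- grid[which.max(eff_ref(360, 35, 27, grid))]
  expect_lt(abs(opt$tr - brute), 0.5)
})

test_that("a TR bound below the unconstrained optimum is returned flagged", {
  tis <- tissue_relaxation(360, 35)
  free <- optimal_tr(tis, te = 27, tr_bounds = c(27, 3000))
  capped <- optimal_tr(tis, te = 27, tr_bounds = c(27, free$tr - 100))
  expect_equal(capped$tr, free$tr - 100, tolerance = 1e-6)
  expect_true(capped$boundary)
  expect_error(optimal_tr(tis, te = 27, tr_bounds = c(10, 3000)), "bounds")
})

test_that("optimal concentration and its interval match the grid oracle", {
  ci <- optimal_concentration(cortex2$t1, cortex2$t2, te = 27, tr = 250)
  # brute-force oracle at 0.5 mM resolution with bisection-level refinement
  g <- seq(0, 100, by = 0.01)
  v <- eff_ref(rt_ref(896, 0.167, g), rt_ref(46.8, 0.801, g), 27, 250)
  i <- which.max(v)
  expect_lt(abs(ci$argmax - g[i]), 0.5)
  lvl <- g[v >= 0.95 * v[i]]
  expect_lt(abs(ci$lo - min(lvl)), 0.1)
  expect_lt(abs(ci$hi - max(lvl)), 0.1)
  # frozen values for the cortex 2% PFA record at TE/TR = 27/250
  expect_equal(ci$argmax, 20.2, tolerance = 0.05)
  expect_equal(ci$lo, 12.3, tolerance = 0.05)
  expect_equal(ci$hi, 30.3, tolerance = 0.05)
  # CC record argmax at the same timing
  ci_cc <- optimal_concentration(cc2$t1, cc2$t2, te = 27, tr = 250)
  expect_equal(ci_cc$argmax, 35.1, tolerance = 0.05)
  # interval endpoints evaluate to the threshold within 0.5% relative
  effc <- function(c) eff_ref(rt_ref(896, 0.167, c), rt_ref(46.8, 0.801, c),
                              27, 250)
  expect_lt(abs(effc(ci$lo) - 0.95 * ci$max_efficiency) /
              (0.95 * ci$max_efficiency), 0.005)
  expect_lt(abs(effc(ci$hi) - 0.95 * ci$max_efficiency) /
              (0.95 * ci$max_efficiency), 0.005)
})

test_that("zero T2 relaxivity pushes the optimum to the upper bound, flagged", {
  p1 <- relaxivity_params(896, 0.167, "T1")
  p2 <- relaxivity_params(46.8, 0, "T2")
  ci <- optimal_concentration(p1, p2, te = 27, tr = 250,
                              ca_bounds = c(0, 60))
  expect_equal(ci$argmax, 60)
  expect_true(ci$argmax_at_bound)
  expect_true(ci$bounded_hi)
})

test_that("efficiency surface is dense, masked and consistent with the planner", {
  te_grid <- seq(10, 40, by = 5)
  tr_grid <- seq(100, 1000, by = 100)
  ca_grid <- seq(0, 80, by = 0.5)
  s <- efficiency_surface(cortex2$t1, cortex2$t2, te_grid, tr_grid, ca_grid)
  # masked exactly where tr < te (here: no such cells since min tr = 100)
  expect_false(any(is.na(s$values)))
  s2 <- efficiency_surface(cortex2$t1, cortex2$t2, c(20, 50), c(30, 300),
                           c(0, 10))
  expect_true(all(is.na(s2$values[2, 1, ])))   # te = 50 > tr = 30: masked
  expect_false(anyNA(s2$values[1, 1, ]))       # te = 20 <= tr = 30: valid
  # single-cell grids reduce to the scalar efficiency
  one <- efficiency_surface(cortex2$t1, cortex2$t2, 27, 250, 15)
  expect_equal(as.numeric(one$values),
               eff_ref(rt_ref(896, 0.167, 15), rt_ref(46.8, 0.801, 15),
                       27, 250), tolerance = 1e-12)
  # per-cell optimal concentration decreases along TE and along TR
  for (j in seq_along(tr_grid))
    expect_true(all(diff(s$opt_ca[, j]) <= 0))
  for (i in seq_along(te_grid))
    expect_true(all(diff(s$opt_ca[i, ]) <= 0))
  # grid argmax agrees with optimal_concentration at a sample cell
  ci <- optimal_concentration(cortex2$t1, cortex2$t2, te = 20, tr = 300,
                              ca_bounds = c(0, 80))
  expect_lt(abs(s$opt_ca[3, 3] - ci$argmax), 0.5)
  expect_error(efficiency_surface(cortex2$t1, cortex2$t2, 100, 50, 10),
               "tr < te")
})

test_that("matched TR reproduces the reference per-excitation signal", {
  sq <- sequence_params(te = 26.78, tr = 250)
  # identity: matching a tissue against itself returns the reference TR
  expect_equal(matched_tr(opt_tissue, sq, opt_tissue), 250, tolerance = 1e-4)
  # the gadolinium-free 4% PFA preparation needs a much longer TR
  tr_full <- matched_tr(opt_tissue, sq, std_tissue)
  tr_simple <- matched_tr(opt_tissue, sq, std_tissue, "simple")
  expect_equal(tr_full, 780.4, tolerance = 1e-3)
  expect_equal(tr_simple, 833.0, tolerance = 1e-3)
  # exact inverse: plugging the result back reproduces the signal to 1e-6
  s_ref <- as.numeric(spin_echo_signal(opt_tissue, 26.78, 250))
  s_back <- as.numeric(spin_echo_signal(std_tissue, 26.78, tr_full))
  expect_lt(abs(s_back - s_ref) / s_ref, 1e-6)
  # unreachable reference signal names the asymptote
  weak <- tissue_relaxation(1705, 10)   # e^{-te/t2} far below the reference
  expect_error(matched_tr(opt_tissue, sq, weak), "asymptote")
})

test_that("predicted SNR scales by the signal ratio and sqrt(averages)", {
  sq <- sequence_params(te = 26.78, tr = 250)
  expect_equal(predict_snr(12, opt_tissue, opt_tissue, sq), 12)
  # the standard preparation at the optimized protocol drops below 5
  expect_equal(predict_snr(12, opt_tissue, std_tissue, sq), 4.12,
               tolerance = 1e-2)
  expect_equal(predict_snr(10, opt_tissue, opt_tissue, sq,
                           averages_ratio = 4), 20)
  expect_error(predict_snr(0, opt_tissue, std_tissue, sq), "measured_snr")
})

test_that("scan time scales linearly in TR and averages", {
  expect_equal(scale_scan_time(91.35, tr_ratio = 750 / 250), 274.05)
  expect_equal(scale_scan_time(9.13, averages_ratio = 1 / 4), 2.2825)
  expect_equal(scale_scan_time(5), 5)
  expect_error(scale_scan_time(5, tr_ratio = 0), "ratios")
})

test_that("optimizers match exhaustive search on random parameter sets", {
  set.seed(2024)
  for (k in 1:20) {
    t10 <- stats::runif(1, 300, 1800)
    r1 <- stats::runif(1, 0.05, 0.4)
    t20 <- stats::runif(1, 25, 70)
    r2 <- stats::runif(1, 0.3, 1.0)
    te <- stats::runif(1, 10, 35)
    tr <- stats::runif(1, 100, 900)
    p1 <- relaxivity_params(t10, r1, "T1")
    p2 <- relaxivity_params(t20, r2, "T2")
    ci <- optimal_concentration(p1, p2, te, tr)
    g <- seq(0, 100, by = 0.1)
    v <- eff_ref(rt_ref(t10, r1, g), rt_ref(t20, r2, g), te, tr)
    expect_lt(abs(ci$argmax - g[which.max(v)]), 0.2)
    # TR optimizer against a 0.5 ms grid
    tis <- tissue_relaxation(rt_ref(t10, r1, 20), rt_ref(t20, r2, 20))
    opt <- optimal_tr(tis, te)
    gt <- seq(te, 10000, by = 0.5)
    expect_lt(abs(opt$tr - gt[which.max(eff_ref(tis$t1, tis$t2, te, gt))]),
              1)
  }
})

test_that("gadobutrol baselines sit at the expected fraction of Gd-DTPA's", {
  r_t1 <- agent_baseline_ratios(records, which = "T1")
  expect_gte(min(r_t1$ratio), 0.4)
  expect_lte(max(r_t1$ratio), 0.5)
  r_t2 <- agent_baseline_ratios(records, which = "T2")
  expect_equal(round(r_t2$ratio[r_t2$tissue == "CC"], 1), 0.7)
})

test_that("plan_protocol assembles a coherent report", {
  plan <- plan_protocol(cortex2$t1, cortex2$t2, te = 27, tr = 250)
  expect_s3_class(plan, "plan_report")
  expect_equal(plan$ca, plan$interval$argmax)
  expect_equal(plan$tissue$t1, relaxation_time(cortex2$t1, plan$ca))
  expect_equal(plan$efficiency,
               as.numeric(snr_efficiency(plan$tissue, 27, 250)),
               tolerance = 1e-9)
})
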