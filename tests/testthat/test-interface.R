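test_that("packaged relaxivity records load with all nine preparations", {
  rec <- load_relaxivity_records()
  expect_identical(nrow(rec), 9L)
  expect_setequal(unique(rec$tissue), c("CC", "cortex", "thalamus"))
  cc2pct <- rec[rec$tissue == "CC" & rec$fixative_pct == 2 &
                  rec$agent == "Gd-DTPA", ]
  expect_equal(c(cc2pct$T10, cc2pct$r1, cc2pct$T20, cc2pct$r2),
               c(876, 0.109, 45.0, 0.444))
  cc4pct <- rec[rec$tissue == "CC" & rec$fixative_pct == 4, ]
  expect_equal(c(cc4pct$T10, cc4pct$r1, cc4pct$T20, cc4pct$r2),
               c(707, 0.120, 35.8, 0.703))
  ccgado <- rec[rec$tissue == "CC" & rec$agent == "gadobutrol", ]
  expect_equal(c(ccgado$T10, ccgado$r1, ccgado$T20, ccgado$r2),
               c(354, 0.267, 30.4, 0.438))
  expect_error(get_relaxivity_pair(rec, "hippocampus"), "no record")
})

test_that("relaxivity records round-trip through JSON", {
  rec <- load_relaxivity_records()
  path <- tempfile(fileext = ".json")
  write_relaxivity_records(rec, path)
  back <- load_relaxivity_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
  # a fitted pair serializes into the same schema
  pair_path <- tempfile(fileext = ".json")
  write_relaxivity_records(cc2, pair_path)
  pair_back <- get_relaxivity_pair(load_relaxivity_records(pair_path),
                                   "CC", 2, "Gd-DTPA")
  expect_equal(pair_back$t1$baseline_time, 876)
  expect_equal(pair_back$t2$relaxivity, 0.444)
})

test_that("acquisition series round-trip through NIfTI + sidecar", {
  spec <- phantom_spec(shape = c(6L, 6L, 2L), noise_sigma = 5, seed = 17)
  series <- make_relaxometry_series(spec, "multi_echo")
  dir <- withr::local_tempdir()
  img <- file.path(dir, "series.nii.gz")
  write_series(series, img)
  back <- read_series(img)
  expect_identical(back$kind, "multi_echo")
  expect_equal(back$control_values, series$control_values)
  expect_equal(back$signals, series$signals, tolerance = 1e-6)
  expect_equal(back$dim, c(6L, 6L, 2L))
})

test_that("simulate then fit-t2 then roi-stats recovers phantom truth", {
  dir <- withr::local_tempdir()
  sim <- file.path(dir, "sim"); fit <- file.path(dir, "fit")
  roi <- file.path(dir, "roi")
  expect_identical(run_command(c("simulate", "--kind", "multi_echo",
                                 "--noise-sigma", "5", "--seed", "11",
                                 "--out", sim)), 0L)
  expect_true(file.exists(file.path(sim, "series.nii.gz")))
  expect_true(file.exists(file.path(sim, "provenance.json")))
  expect_identical(run_command(c("fit-t2", "--image",
                                 file.path(sim, "series.nii.gz"),
                                 "--out", fit)), 0L)
  expect_identical(run_command(c("roi-stats", "--map",
                                 file.path(fit, "t2_map.nii.gz"),
                                 "--mask", file.path(sim, "mask_CC.nii.gz"),
                                 "--label", "CC", "--out", roi)), 0L)
  st <- utils::read.csv(file.path(roi, "roi_stats.csv"))
  expect_lt(abs(st$mean - 45.0), 1)   # CC truth T2 = 45 ms

  # kind mismatch is an input error (exit 2)
  expect_identical(run_command(c("fit-t1", "--image",
                                 file.path(sim, "series.nii.gz"),
                                 "--out", fit)), 2L)
})

test_that("cohort simulation feeds the relaxivity and rehydration commands", {
  dir <- withr::local_tempdir()
  sim <- file.path(dir, "sim"); out <- file.path(dir, "fit")
  expect_identical(run_command(c("simulate", "--cohort", "relaxivity",
                                 "--tissue", "CC", "--seed", "3",
                                 "--out", sim)), 0L)
  expect_identical(run_command(c("relaxivity", "--cohort",
                                 file.path(sim, "cohort.csv"),
                                 "--out", out)), 0L)
  fit <- jsonlite::fromJSON(file.path(out, "relaxivity_fit.json"))
  expect_equal(fit$T10, 876, tolerance = 1e-6)
  expect_equal(fit$r2, 0.444, tolerance = 1e-6)

  sim2 <- file.path(dir, "sim2"); out2 <- file.path(dir, "fit2")
  expect_identical(run_command(c("simulate", "--cohort", "rehydration",
                                 "--seed", "4", "--out", sim2)), 0L)
  expect_identical(run_command(c("rehydration", "--cohort",
                                 file.path(sim2, "cohort.csv"),
                                 "--out", out2)), 0L)
  rh <- jsonlite::fromJSON(file.path(out2, "rehydration_fit.json"))
  expect_equal(rh$plateau, 52, tolerance = 1e-6)
  expect_equal(rh$t95, 7 * log(22 / (0.05 * 52)), tolerance = 1e-6)
})

test_that("plan command writes a report consistent with the planner", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "plan")
  expect_identical(run_command(c("plan", "--tissue", "cortex",
                                 "--te", "27", "--tr", "250",
                                 "--out", out)), 0L)
  plan <- jsonlite::fromJSON(file.path(out, "plan.json"))
  ref <- plan_protocol(cortex2$t1, cortex2$t2, 27, 250)
  expect_equal(plan$ca, ref$ca, tolerance = 1e-6)
  expect_equal(plan$ca_interval, c(ref$interval$lo, ref$interval$hi),
               tolerance = 1e-6)
  expect_equal(plan$predicted_t1, ref$tissue$t1, tolerance = 1e-6)

  # unknown tissue label is a schema/input error (exit 2)
  expect_identical(run_command(c("plan", "--tissue", "liver", "--te", "27",
                                 "--tr", "250", "--out", out)), 2L)
  # tr < te violates the spin-echo constraint (exit 4)
  expect_identical(run_command(c("plan", "--tissue", "CC", "--te", "27",
                                 "--tr", "10", "--out", out)), 4L)
})

test_that("matched-tr and snr commands produce the module results", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "mtr")
  expect_identical(run_command(c("matched-tr",
                                 "--ref-t1", "360.16", "--ref-t2", "34.62",
                                 "--target-t1", "1705", "--target-t2", "52",
                                 "--te", "26.78", "--tr", "250",
                                 "--out", out)), 0L)
  res <- jsonlite::fromJSON(file.path(out, "matched_tr.json"))
  expect_equal(res$matched_tr, 780.4, tolerance = 1e-3)
  # unreachable target signal -> constraint violation (exit 4)
  expect_identical(run_command(c("matched-tr",
                                 "--ref-t1", "360.16", "--ref-t2", "34.62",
                                 "--target-t1", "1705", "--target-t2", "10",
                                 "--te", "26.78", "--tr", "250",
                                 "--out", out)), 4L)

  set.seed(8)
  img <- array(0, dim = c(20, 20, 4))
  sig <- array(FALSE, dim = dim(img)); sig[1:6, 1:6, ] <- TRUE
  noi <- array(FALSE, dim = dim(img)); noi[12:20, 12:20, ] <- TRUE
  img[sig] <- 100
  img[noi] <- sqrt(stats::rnorm(sum(noi), 0, 10)^2 +
                     stats::rnorm(sum(noi), 0, 10)^2)
  snrdir <- file.path(dir, "snr")
  RNifti::writeNifti(RNifti::asNifti(img), file.path(dir, "img.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(sig), dim = dim(img))),
                     file.path(dir, "sig.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(noi), dim = dim(img))),
                     file.path(dir, "noi.nii.gz"))
  expect_identical(run_command(c("snr", "--image", file.path(dir, "img.nii.gz"),
                                 "--signal-mask", file.path(dir, "sig.nii.gz"),
                                 "--noise-mask", file.path(dir, "noi.nii.gz"),
                                 "--out", snrdir)), 0L)
  sn <- utils::read.csv(file.path(snrdir, "snr.csv"))
  expect_equal(sn$snr, 10, tolerance = 0.15)

  # missing input file -> exit 2; unknown command -> exit 2
  expect_identical(run_command(c("snr", "--image", "nope.nii",
                                 "--signal-mask", "a", "--noise-mask", "b")),
                   2L)
  expect_identical(suppressMessages(run_command("frobnicate")), 2L)
})

test_that("identical config and seed give identical outputs", {
  dir <- withr::local_tempdir()
  a <- file.path(dir, "a"); b <- file.path(dir, "b")
  for (o in c(a, b))
    run_command(c("simulate", "--cohort", "relaxivity", "--seed", "12",
                  "--noise-sd", "30", "--out", o))
  expect_identical(readLines(file.path(a, "cohort.csv")),
                   readLines(file.path(b, "cohort.csv")))
})
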