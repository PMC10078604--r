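# Command-line style interface: readers/writers for the on-disk formats
# (NIfTI images, CSV sidecars and cohorts, JSON model records) and a
# dispatcher tying the stages into reproducible runs.
#
# Exit codes: 0 ok, 2 input error, 3 fit non-convergence, 4 constraint
# violation. Errors raised with the matching condition classes
# ("relaxoplan_input_error", "relaxoplan_fit_error",
# "relaxoplan_constraint_error") are mapped to these codes by run_command().

.input_error <- function(...) {
  stop(structure(class = c("relaxoplan_input_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}
.fit_error <- function(...) {
  stop(structure(class = c("relaxoplan_fit_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}
.constraint_error <- function(...) {
  stop(structure(class = c("relaxoplan_constraint_error", "error",
                           "condition"),
                 list(message = sprintf(...), call = NULL)))
}

#' Write / read an acquisition series as NIfTI + sidecar
#'
#' The image stack goes to a NIfTI file (last dimension indexing volumes)
#' and the control values (TR or TE list) to a CSV sidecar with columns
#' `volume` and `control_ms`, plus the series kind.
#'
#' @param series An [acquisition_series()] (must carry spatial dimensions).
#' @param image_path Path for the `.nii`/`.nii.gz` stack.
#' @param sidecar_path Path for the CSV sidecar; defaults to the image path
#'   with extension replaced by `.csv`.
#' @return `write_series()` returns the paths invisibly; `read_series()`
#'   returns an [acquisition_series()].
#' @export
write_series <- function(series, image_path, sidecar_path = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  if (is.null(series$dim))
    .input_error("series has no spatial dimensions; cannot write an image")
  if (is.null(sidecar_path)) sidecar_path <- .sidecar_of(image_path)
  img <- array(series$signals, dim = c(series$dim, ncol(series$signals)))
  RNifti::writeNifti(RNifti::asNifti(img), image_path)
  utils::write.csv(
    data.frame(volume = seq_along(series$control_values),
               control_ms = series$control_values,
               kind = series$kind),
    sidecar_path, row.names = FALSE)
  invisible(c(image = image_path, sidecar = sidecar_path))
}

.sidecar_of <- function(image_path) {
  sub("\\.nii(\\.gz)?$", ".csv", image_path)
}

#' @rdname write_series
#' @export
read_series <- function(image_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- .sidecar_of(image_path)
  if (!file.exists(image_path)) .input_error("missing image: %s", image_path)
  if (!file.exists(sidecar_path))
    .input_error("missing sidecar: %s", sidecar_path)
  img <- as.array(RNifti::readNifti(image_path))
  sc <- utils::read.csv(sidecar_path, stringsAsFactors = FALSE)
  if (!all(c("control_ms", "kind") %in% names(sc)))
    .input_error("sidecar must have columns control_ms and kind")
  kind <- unique(sc$kind)
  if (length(kind) != 1L || !kind %in% c("multi_echo", "variable_tr"))
    .input_error("sidecar kind must be 'multi_echo' or 'variable_tr'")
  acquisition_series(img, sc$control_ms, kind)
}

#' Read a binary mask volume
#'
#' @param path NIfTI mask file; any non-zero voxel is in the mask.
#' @return Logical array.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) .input_error("missing mask: %s", path)
  as.array(RNifti::readNifti(path)) != 0
}

# Provenance record written next to every command's outputs.
.write_provenance <- function(outdir, command, args, seed = NULL) {
  rec <- list(package = "relaxoplan",
              version = as.character(utils::packageVersion("relaxoplan")),
              command = command,
              args = as.list(args),
              seed = seed,
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(rec, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
}

# Minimal --flag value parser; flags lose the leading "--" and "-" becomes
# "_". Bare flags (no value) become TRUE.
.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      .input_error("unexpected argument '%s' (expected --flag value)", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

.flag_num <- function(flags, name, default = NULL) {
  if (is.null(flags[[name]])) {
    if (is.null(default)) .input_error("missing required flag --%s",
                                       gsub("_", "-", name))
    return(default)
  }
  v <- suppressWarnings(as.numeric(flags[[name]]))
  if (is.na(v)) .input_error("flag --%s must be numeric",
                             gsub("_", "-", name))
  v
}

.flag_chr <- function(flags, name, default = NULL) {
  if (is.null(flags[[name]])) {
    if (is.null(default)) .input_error("missing required flag --%s",
                                       gsub("_", "-", name))
    return(default)
  }
  as.character(flags[[name]])
}

.need_outdir <- function(flags) {
  outdir <- .flag_chr(flags, "out", "relaxoplan-out")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outdir
}

#' Run a relaxoplan command
#'
#' Dispatches one of the package's subcommands from a character vector of
#' command-line arguments, writes its artifacts into the `--out` directory
#' (with a `provenance.json` recording the package version, arguments and
#' seed), and returns an exit status: 0 on success, 2 for input errors, 3
#' for fit non-convergence, 4 for constraint violations.
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate`}{`--kind multi_echo|variable_tr --noise-sigma s --seed i
#'     [--out dir]`: phantom series written as NIfTI + sidecar, or
#'     `--cohort relaxivity|rehydration` for CSV cohorts.}
#'   \item{`fit-t1`, `fit-t2`}{`--image x.nii [--sidecar x.csv] [--out dir]`:
#'     voxelwise map fitting; writes parameter and quality NIfTI maps.}
#'   \item{`roi-stats`}{`--map map.nii --mask m.nii [--label L]`: ROI
#'     mean/SD as CSV.}
#'   \item{`relaxivity`}{`--cohort c.csv [--which T1]`: relaxivity model fit,
#'     written as a JSON record.}
#'   \item{`rehydration`}{`--cohort c.csv`: exponential recovery fit with
#'     t95, written as JSON.}
#'   \item{`plan`}{`--params records.json --tissue CC --fixative 2
#'     --agent Gd-DTPA --te ms --tr ms [--ca-max mM] [--threshold 0.95]
#'     [--variant full]`: optimal concentration plan, written as JSON.}
#'   \item{`matched-tr`}{`--ref-t1 --ref-t2 --target-t1 --target-t2 --te
#'     --tr [--variant full]`: TR matching the reference signal, as JSON.}
#'   \item{`snr`}{`--image x.nii --signal-mask s.nii --noise-mask n.nii`:
#'     background-noise SNR estimate as CSV.}
#' }
#'
#' @param args Character vector: subcommand followed by `--flag value`
#'   pairs, e.g. `c("plan", "--params", "r.json", "--te", "27", ...)`.
#' @return Integer exit status, invisibly. Command errors are caught and
#'   reported on stderr; unexpected internal errors are re-signalled.
#' @export
run_command <- function(args) {
  if (!length(args)) {
    message("usage: relaxoplan <simulate|fit-t1|fit-t2|roi-stats|relaxivity|",
            "rehydration|plan|matched-tr|snr> [--flag value ...]")
    return(invisible(2L))
  }
  command <- args[[1L]]
  handler <- switch(command,
    "simulate" = .cmd_simulate,
    "fit-t1" = function(f) .cmd_fit_map(f, "variable_tr"),
    "fit-t2" = function(f) .cmd_fit_map(f, "multi_echo"),
    "roi-stats" = .cmd_roi_stats,
    "relaxivity" = .cmd_relaxivity,
    "rehydration" = .cmd_rehydration,
    "plan" = .cmd_plan,
    "matched-tr" = .cmd_matched_tr,
    "snr" = .cmd_snr,
    NULL)
  if (is.null(handler)) {
    message("unknown command: ", command)
    return(invisible(2L))
  }
  status <- tryCatch({
    flags <- .parse_flags(args[-1L])
    handler(flags)
    0L
  },
  relaxoplan_input_error = function(e) { message("input error: ",
                                                 conditionMessage(e)); 2L },
  relaxoplan_fit_error = function(e) { message("fit error: ",
                                               conditionMessage(e)); 3L },
  relaxoplan_constraint_error = function(e) {
    message("constraint violation: ", conditionMessage(e)); 4L },
  error = function(e) { message("input error: ", conditionMessage(e)); 2L })
  invisible(status)
}

.cmd_simulate <- function(flags) {
  outdir <- .need_outdir(flags)
  seed <- as.integer(.flag_num(flags, "seed", 1))
  cohort <- .flag_chr(flags, "cohort", "")
  if (nzchar(cohort)) {
    if (cohort == "relaxivity") {
      rec <- load_relaxivity_records()
      pair <- get_relaxivity_pair(rec, .flag_chr(flags, "tissue", "CC"),
                                  .flag_num(flags, "fixative", 2),
                                  .flag_chr(flags, "agent", "Gd-DTPA"))
      tab <- make_relaxivity_cohort(pair$t1, pair$t2,
                                    n_per_ca = as.integer(
                                      .flag_num(flags, "n_per_ca", 2)),
                                    noise_sd = .flag_num(flags, "noise_sd", 0),
                                    seed = seed)
    } else if (cohort == "rehydration") {
      truth <- list(plateau = .flag_num(flags, "plateau", 52),
                    amplitude = .flag_num(flags, "amplitude", 22),
                    time_constant = .flag_num(flags, "tau", 7))
      tab <- make_rehydration_series(truth,
                                     noise_sd = .flag_num(flags, "noise_sd", 0),
                                     seed = seed)
    } else .input_error("unknown cohort type '%s'", cohort)
    write_cohort_csv(tab, file.path(outdir, "cohort.csv"))
  } else {
    kind <- .flag_chr(flags, "kind", "multi_echo")
    if (!kind %in% c("multi_echo", "variable_tr"))
      .input_error("unknown series kind '%s'", kind)
    spec <- phantom_spec(noise_sigma = .flag_num(flags, "noise_sigma", 0),
                         seed = seed)
    series <- make_relaxometry_series(spec, kind)
    write_series(series, file.path(outdir, "series.nii.gz"))
    for (r in spec$truth$name) {
      RNifti::writeNifti(
        RNifti::asNifti(array(as.integer(phantom_mask(spec, r)),
                              dim = spec$shape)),
        file.path(outdir, paste0("mask_", r, ".nii.gz")))
    }
  }
  .write_provenance(outdir, "simulate", flags, seed)
}

.cmd_fit_map <- function(flags, kind) {
  outdir <- .need_outdir(flags)
  series <- read_series(.flag_chr(flags, "image"),
                        flags[["sidecar"]])
  if (series$kind != kind)
    .input_error("series kind is '%s' but the command expects '%s'",
                 series$kind, kind)
  map <- fit_map(series)
  if (map$n_nonconverged == length(map$values))
    .fit_error("no voxel converged")
  RNifti::writeNifti(RNifti::asNifti(map$values),
                     file.path(outdir, paste0(tolower(map$kind), "_map.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(map$quality),
                     file.path(outdir, "stderr_map.nii.gz"))
  jsonlite::write_json(list(kind = map$kind,
                            n_nonconverged = map$n_nonconverged),
                       file.path(outdir, "fit_summary.json"),
                       auto_unbox = TRUE)
  .write_provenance(outdir, paste0("fit-", tolower(map$kind)), flags)
}

.cmd_roi_stats <- function(flags) {
  outdir <- .need_outdir(flags)
  map_path <- .flag_chr(flags, "map")
  if (!file.exists(map_path)) .input_error("missing map: %s", map_path)
  values <- as.array(RNifti::readNifti(map_path))
  mask <- read_mask(.flag_chr(flags, "mask"))
  st <- roi_stats(values, mask, .flag_chr(flags, "label", "ROI"))
  utils::write.csv(
    data.frame(roi = st$roi_label, mean = st$mean, sd = st$sd,
               n_voxels = st$n_voxels, n_excluded = st$n_excluded),
    file.path(outdir, "roi_stats.csv"), row.names = FALSE)
  .write_provenance(outdir, "roi-stats", flags)
}

.cmd_relaxivity <- function(flags) {
  outdir <- .need_outdir(flags)
  tab <- read_cohort_csv(.flag_chr(flags, "cohort"))
  which <- flags[["which"]]
  arms <- if (is.null(which)) unique(tab$which) else which
  fits <- lapply(arms, function(w)
    fit_relaxivity(structure(tab[tab$which == w, ],
                             class = c("cohort_table", "data.frame")), w))
  names(fits) <- arms
  if (all(c("T1", "T2") %in% arms)) {
    write_relaxivity_records(list(t1 = fits[["T1"]], t2 = fits[["T2"]]),
                             file.path(outdir, "relaxivity_fit.json"))
  } else {
    f <- fits[[1L]]
    jsonlite::write_json(list(which = f$which, baseline_time = f$baseline_time,
                              relaxivity = f$relaxivity,
                              fit_stderr = f$fit_stderr),
                         file.path(outdir, "relaxivity_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  .write_provenance(outdir, "relaxivity", flags)
}

.cmd_rehydration <- function(flags) {
  outdir <- .need_outdir(flags)
  tab <- read_cohort_csv(.flag_chr(flags, "cohort"))
  fit <- fit_rehydration(tab)
  if (!isTRUE(fit$converged)) .fit_error("rehydration fit did not converge")
  jsonlite::write_json(list(plateau = fit$plateau, amplitude = fit$amplitude,
                            time_constant = fit$time_constant, t95 = fit$t95,
                            stderr = fit$stderr),
                       file.path(outdir, "rehydration_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_provenance(outdir, "rehydration", flags)
}

.cmd_plan <- function(flags) {
  outdir <- .need_outdir(flags)
  rec <- load_relaxivity_records(flags[["params"]])
  tissue <- .flag_chr(flags, "tissue", "CC")
  if (!tissue %in% rec$tissue)
    .input_error("unknown tissue label '%s' in the records", tissue)
  pair <- tryCatch(
    get_relaxivity_pair(rec, tissue, .flag_num(flags, "fixative", 2),
                        .flag_chr(flags, "agent", "Gd-DTPA")),
    error = function(e) .input_error("%s", conditionMessage(e)))
  te <- .flag_num(flags, "te"); tr <- .flag_num(flags, "tr")
  if (tr < te) .constraint_error("tr (%g) must be >= te (%g)", tr, te)
  plan <- plan_protocol(pair$t1, pair$t2, te, tr,
                        ca_bounds = c(0, .flag_num(flags, "ca_max", 100)),
                        variant = .flag_chr(flags, "variant", "full"),
                        threshold_fraction = .flag_num(flags, "threshold",
                                                       0.95))
  ci <- plan$interval
  jsonlite::write_json(
    list(tissue = tissue, te = te, tr = tr, variant = plan$variant,
         ca = plan$ca, ca_interval = c(ci$lo, ci$hi),
         threshold_fraction = ci$threshold_fraction,
         bounded = list(lo = ci$bounded_lo, hi = ci$bounded_hi),
         argmax_at_bound = ci$argmax_at_bound,
         predicted_t1 = plan$tissue$t1, predicted_t2 = plan$tissue$t2,
         efficiency = plan$efficiency),
    file.path(outdir, "plan.json"), auto_unbox = TRUE, digits = NA)
  .write_provenance(outdir, "plan", flags)
}

.cmd_matched_tr <- function(flags) {
  outdir <- .need_outdir(flags)
  ref <- tissue_relaxation(.flag_num(flags, "ref_t1"),
                           .flag_num(flags, "ref_t2"))
  tgt <- tissue_relaxation(.flag_num(flags, "target_t1"),
                           .flag_num(flags, "target_t2"))
  sq <- sequence_params(.flag_num(flags, "te"), .flag_num(flags, "tr"))
  tr <- tryCatch(
    matched_tr(ref, sq, tgt, .flag_chr(flags, "variant", "full")),
    error = function(e) .constraint_error("%s", conditionMessage(e)))
  jsonlite::write_json(list(matched_tr = tr, te = sq$te,
                            reference_tr = sq$tr),
                       file.path(outdir, "matched_tr.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_provenance(outdir, "matched-tr", flags)
}

.cmd_snr <- function(flags) {
  outdir <- .need_outdir(flags)
  img_path <- .flag_chr(flags, "image")
  if (!file.exists(img_path)) .input_error("missing image: %s", img_path)
  img <- as.array(RNifti::readNifti(img_path))
  m <- measure_rois(img, read_mask(.flag_chr(flags, "signal_mask")),
                    read_mask(.flag_chr(flags, "noise_mask")),
                    .flag_chr(flags, "label", "ROI"))
  utils::write.csv(
    data.frame(roi = m$roi_label, signal_mean = m$signal_mean,
               noise_sd = m$noise_sd, snr = m$snr,
               n_signal = m$n_signal, n_noise = m$n_noise),
    file.path(outdir, "snr.csv"), row.names = FALSE)
  .write_provenance(outdir, "snr", flags)
}
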