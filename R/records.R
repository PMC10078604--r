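# Packaged relaxivity model records and their JSON schema.

#' Load the packaged relaxivity model records
#'
#' The package ships fitted relaxivity-model parameters for nine
#' tissue/fixative/agent combinations of ex vivo rat brain (corpus callosum,
#' cortex and thalamus; 4% and 2% PFA with Gd-DTPA, and 2% PFA with
#' gadobutrol). Each record holds both arms of the model: baseline times
#' `T10`/`T20` (ms), relaxivities `r1`/`r2` (1/(mM s)) and regression
#' standard errors `sigma1`/`sigma2` (ms).
#'
#' @param path Optional path to a JSON file in the same schema; defaults to
#'   the packaged records.
#' @return A data frame with columns `fixative_pct`, `agent`, `tissue`,
#'   `T10`, `r1`, `sigma1`, `T20`, `r2`, `sigma2`.
#' @seealso [get_relaxivity_pair()] to pull one record as a pair of
#'   [relaxivity_params()] objects.
#' @export
#' @examples
#' load_relaxivity_records()
load_relaxivity_records <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "relaxivity_records.json",
                        package = "relaxoplan", mustWork = TRUE)
  rec <- jsonlite::fromJSON(path)
  need <- c("fixative_pct", "agent", "tissue", "T10", "r1", "sigma1",
            "T20", "r2", "sigma2")
  if (!all(need %in% names(rec)))
    stop("relaxivity records must have fields: ",
         paste(need, collapse = ", "), call. = FALSE)
  rec[need]
}

#' Extract one record as a T1/T2 parameter pair
#'
#' @param records A record table from [load_relaxivity_records()].
#' @param tissue,fixative_pct,agent Selectors identifying one record.
#' @return A list with elements `t1` and `t2`, both [relaxivity_params()].
#' @export
#' @examples
#' pair <- get_relaxivity_pair(load_relaxivity_records(), "CC", 2, "Gd-DTPA")
#' relaxation_time(pair$t1, 15)
get_relaxivity_pair <- function(records, tissue, fixative_pct = 2,
                                agent = "Gd-DTPA") {
  sel <- records$tissue == tissue & records$fixative_pct == fixative_pct &
    records$agent == agent
  if (sum(sel) == 0L)
    stop(sprintf("no record for tissue '%s', %s%% PFA, %s", tissue,
                 format(fixative_pct), agent), call. = FALSE)
  if (sum(sel) > 1L)
    stop("selectors match more than one record", call. = FALSE)
  r <- records[sel, ]
  list(t1 = relaxivity_params(r$T10, r$r1, "T1", tissue = r$tissue,
                              fixative_pct = r$fixative_pct, agent = r$agent,
                              fit_stderr = r$sigma1),
       t2 = relaxivity_params(r$T20, r$r2, "T2", tissue = r$tissue,
                              fixative_pct = r$fixative_pct, agent = r$agent,
                              fit_stderr = r$sigma2))
}

#' Write relaxivity records to JSON
#'
#' Serializes a record table (or a single [relaxivity_params()] pair) back
#' to the packaged JSON schema, so that fitted models can be reused as
#' planner inputs.
#'
#' @param records Data frame in the [load_relaxivity_records()] schema, or a
#'   list with elements `t1` and `t2` of class `relaxivity_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relaxivity_records <- function(records, path) {
  if (is.list(records) && !is.data.frame(records) &&
      all(c("t1", "t2") %in% names(records))) {
    p1 <- records$t1; p2 <- records$t2
    records <- data.frame(fixative_pct = p1$fixative_pct, agent = p1$agent,
                          tissue = p1$tissue,
                          T10 = p1$baseline_time, r1 = p1$relaxivity,
                          sigma1 = p1$fit_stderr,
                          T20 = p2$baseline_time, r2 = p2$relaxivity,
                          sigma2 = p2$fit_stderr,
                          stringsAsFactors = FALSE)
  }
  jsonlite::write_json(records, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
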