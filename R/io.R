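#' Read and write cohort tables
#'
#' The cohort interchange format is a plain CSV with one row per patient
#' and phase: columns `patient_id`, `phase` (`before`/`after`), `hr`,
#' `map_mmhg`, `cvp_mmhg`, `co_lmin`, `sv_ml`, then the seven index
#' columns of [index_names()]. `read_cohort()` validates the schema and
#' names the offending column on failure.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort()` returns a validated `fluid_cohort`
#'   `data.frame`; `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(x)
  class(x) <- c("fluid_cohort", "data.frame")
  x
}

#' Read and write beat-by-beat series
#'
#' Beat series CSVs carry columns `time_s`, `sv_ml`, `pp_mmhg` and
#' optionally `pi_pct`.
#'
#' @param series A [beat_series()].
#' @param path File path.
#' @return `read_beat_series()` returns a validated [beat_series()];
#'   `write_beat_series()` returns `path` invisibly.
#' @export
write_beat_series <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  out <- data.frame(time_s = series$t, sv_ml = series$sv,
                    pp_mmhg = series$pp)
  if (!is.null(series$pi)) out$pi_pct <- series$pi
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_series
#' @export
read_beat_series <- function(path) {
  x <- utils::read.csv(path)
  need <- c("time_s", "sv_ml", "pp_mmhg")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("beat series CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  beat_series(x$time_s, x$sv_ml, x$pp_mmhg, pi = x$pi_pct)
}

write_manifest <- function(dir, config) {
  manifest <- c(list(package = "fluidroc",
                     version = as.character(
                       utils::packageVersion("fluidroc")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
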