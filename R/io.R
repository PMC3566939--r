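# column contracts for the delimited-text formats (comma separated, UTF-8,
# '.' decimal separator)
COHORT_REQUIRED <- c("id", "age", "male", "smoking", "bmi", "whr", "sbp",
                     "dbp", "hypertension", "total_chol", "hdl", "glucose",
                     "creatinine", "diabetes", "angina", "atrial_fib",
                     "claudication", "tia", "prevalent_cvd", "fam_hist_mi",
                     "fam_hist_cvd", "abi")
RECORDS_REQUIRED <- c("id", "transition_source", "transition_target",
                      "time_years", "event")
EVENTS_REQUIRED <- c("id", "chd_year", "stroke_year", "cvd_death_year",
                     "non_cvd_death_year", "followup_years")

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), c(required, "baseline_state", "death_cause"))
  if (length(extra)) {
    warning(what, " file '", path, "' has unknown column(s): ",
            paste(extra, collapse = ", "))
  }
  df
}

check_numeric <- function(df, cols, path, allow_na = character(0)) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(v))
      if (length(bad)) {
        stop("malformed numeric cell in '", path, "', column '", cl,
             "', row ", bad[1], ": '", v[bad[1]], "'")
      }
      df[[cl]] <- num
    }
    if (!cl %in% allow_na && anyNA(df[[cl]])) {
      stop("missing value in '", path, "', column '", cl, "', row ",
           which(is.na(df[[cl]]))[1])
    }
  }
  df
}

#' Read and write cohort, follow-up and incidence-surface files
#'
#' All tabular formats are comma-separated UTF-8 text. The cohort file has
#' one row per individual with the 21 risk factors (\code{smoking} as a
#' category) and optionally \code{baseline_state}; follow-up comes as
#' either the long per-transition \emph{records} table or the wide
#' per-individual \emph{events} table; the incidence surface has columns
#' \code{event}, \code{year}, \code{mean}, \code{lo}, \code{hi}. Strict
#' schema validation: missing required columns and malformed numeric cells
#' are errors naming the offender, unknown columns warn. Writing then
#' reading reproduces the values.
#'
#' @param path File path.
#' @param cohort,records,events,surface Objects to write.
#' @return The read functions return validated data frames.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, COHORT_REQUIRED, "cohort", path)
  df <- check_numeric(df, setdiff(COHORT_REQUIRED, c("smoking", "id")), path)
  binaries <- c("male", "hypertension", "diabetes", "angina", "atrial_fib",
                "claudication", "tia", "prevalent_cvd", "fam_hist_mi",
                "fam_hist_cvd")
  for (b in binaries) {
    if (!all(df[[b]] %in% c(0, 1))) {
      stop("cohort column '", b, "' must be 0/1")
    }
  }
  if (any(df$age < 45)) stop("cohort contains ages below 45")
  profile_covariates(df)  # validates smoking categories and coercibility
  ensure_baseline_state(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_followup_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, RECORDS_REQUIRED, "follow-up records", path)
  df <- check_numeric(df, c("time_years", "event"), path)
  if (!all(df$event %in% c(0, 1))) stop("'event' must be 0/1 in ", path)
  if (any(df$time_years <= 0)) stop("non-positive time_years in ", path)
  df
}

#' @rdname read_cohort
#' @export
write_followup_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, EVENTS_REQUIRED, "events", path)
  check_numeric(df, setdiff(EVENTS_REQUIRED, "id"), path,
                allow_na = c("chd_year", "stroke_year", "cvd_death_year",
                             "non_cvd_death_year"))
}

#' @rdname read_cohort
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_surface <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, c("event", "year", "mean", "lo", "hi"),
                      "surface", path)
  df <- check_numeric(df, c("year", "mean", "lo", "hi"), path)
  class(df) <- c("cvd_surface", "data.frame")
  df
}

#' Load a simulation configuration from JSON
#'
#' Omitted fields fall back to the defaults of \code{\link{sim_config}}
#' (100 outer replicates, 2,000 profiles, 200 walks, 13 years).
#'
#' @param path JSON file.
#' @return A \code{\link{sim_config}}.
#' @export
load_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    warning("config '", path, "' has unknown field(s): ",
            paste(unknown, collapse = ", "))
    doc <- doc[intersect(names(doc), known)]
  }
  do.call(sim_config, doc)
}

#' Write a run manifest
#'
#' Every command-line run emits one manifest: the configuration snapshot,
#' seed, md5 digests of the input files, package version and a timestamp,
#' enabling exact re-runs.
#'
#' @param path Output JSON path.
#' @param config A \code{\link{sim_config}} (or any list).
#' @param inputs Named character vector of input file paths.
#' @return The manifest, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0)) {
  manifest <- list(
    package = "cvdsim",
    version = as.character(utils::packageVersion("cvdsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    inputs = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
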