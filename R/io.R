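#' Read a single-patient record from JSON
#'
#' A patient record is a flat JSON object holding the objective fields and
#' the interview answers (and optionally `ahi`). Scalars become one-row
#' tibble columns; nothing is recoded at this layer.
#'
#' @param path Path to a JSON file.
#' @return A one-row tibble.
#' @export
read_patient <- function(path) {
  rec <- jsonlite::read_json(path)
  if (!is.list(rec) || is.null(names(rec))) {
    stop("'", path, "' does not contain a JSON object of named fields",
         call. = FALSE)
  }
  bad <- names(rec)[vapply(rec, function(x) length(x) != 1L, logical(1))]
  if (length(bad)) {
    stop("field(s) ", paste(sQuote(bad), collapse = ", "),
         " in '", path, "' are not scalar", call. = FALSE)
  }
  tibble::as_tibble(lapply(rec, function(x) if (is.null(x)) NA else x))
}

#' Write a single-patient record to JSON
#'
#' @param data A one-row data frame.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_patient <- function(data, path) {
  stopifnot(is.data.frame(data), nrow(data) == 1L)
  jsonlite::write_json(as.list(tibble::as_tibble(data)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path Path to a CSV file with one row per patient.
#' @param require Which column groups must be present: any of `"objective"`
#'   and `"interview"` (default both).
#' @return A tibble.
#' @export
read_cohort <- function(path, require = c("objective", "interview")) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  need <- character()
  fields <- objective_fields()
  if ("objective" %in% require) {
    need <- c(need, "sex", "age", "weight", "height", "neck_circumference",
              "smoker", "drinking", fields$comorbidities, fields$treatments)
  }
  if ("interview" %in% require) need <- c(need, interview_items()$item)
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("cohort file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a cohort or assessment table
#'
#' CSV for tabular exchange, or JSON (by file extension) for single records
#' with full fidelity.
#'
#' @param data A data frame (e.g. an `osa_assessment`).
#' @param path Destination `.csv` or `.json` file.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(data, path) {
  stopifnot(is.data.frame(data))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tibble::as_tibble(data), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(tibble::as_tibble(data), path, row.names = FALSE)
  }
  invisible(path)
}

#' The published case-study patient
#'
#' The worked single-patient example shipped with the package: a 34-year-old
#' male occasional drinker and non-smoker (BMI 24.6, neck 46 cm, no
#' comorbidities or treatments) whose interview reports frequent prolonged
#' awakenings, nocturia and witnessed apneas and habitual high-intensity
#' snoring; his sleep study measured an AHI of 11.90 (below the 15
#' events/hour labeling threshold). Unrecorded habit quantities are stored
#' as 0.
#'
#' @return A one-row tibble with objective fields, interview answers and
#'   `ahi`.
#' @examples
#' case_study_patient()$ahi
#' @export
case_study_patient <- function() {
  read_patient(system.file("extdata", "case_patient.json",
                           package = "osatriage", mustWork = TRUE))
}
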