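COHORT_COLUMNS <- c("id", "age", "pf_ratio", "pmax", "died_in_hospital",
                    "apache_iv", "followup_days", "event_observed",
                    "peep", "fio2")
REQUIRED_COLUMNS <- c("id", "age", "pf_ratio", "pmax", "died_in_hospital")

#' Write a cohort as delimited text
#'
#' Comma-separated, header row, UTF-8, `"."` decimal separator, missing
#' values as empty fields, columns in the fixed order `id, age,
#' pf_ratio, pmax, died_in_hospital, apache_iv, followup_days,
#' event_observed, peep, fio2` (absent optional columns are written
#' empty).
#'
#' @param cohort data.frame of patient records.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- as.data.frame(cohort)[, intersect(COHORT_COLUMNS, names(cohort)),
                               drop = FALSE]
  for (col in setdiff(COHORT_COLUMNS, names(out))) out[[col]] <- NA
  out <- out[, COHORT_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a cohort file
#'
#' Reads a delimited cohort file (format of [write_cohort()]) and
#' validates every record: age >= 18 y, `pf_ratio` > 0 mmHg, `pmax` > 0
#' cmH2O, a boolean death indicator, and — when follow-up is present —
#' an accompanying event indicator consistent with hospital death.
#' Violations raise an error naming the row numbers and fields; unknown
#' columns produce a warning and are dropped.
#'
#' @param path file path.
#' @return data.frame of class `apps_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  for (col in setdiff(COHORT_COLUMNS, names(raw))) raw[[col]] <- NA
  raw <- raw[, COHORT_COLUMNS]
  raw$id <- as.character(raw$id)
  raw$died_in_hospital <- parse_bool(raw$died_in_hospital,
                                     "died_in_hospital")
  raw$event_observed <- parse_bool(raw$event_observed, "event_observed")

  problems <- character(0)
  bad <- function(mask, msg) {
    mask <- !is.na(mask) & mask
    if (any(mask)) {
      problems <<- c(problems, paste0(
        "rows ", paste(utils::head(which(mask), 5), collapse = ","),
        if (sum(mask) > 5) ",..." else "", ": ", msg))
    }
  }
  bad(is.na(raw$age) | raw$age < 18, "age missing or below 18")
  bad(is.na(raw$pf_ratio) | raw$pf_ratio <= 0,
      "pf_ratio missing or non-positive")
  bad(is.na(raw$pmax) | raw$pmax <= 0, "pmax missing or non-positive")
  bad(is.na(raw$died_in_hospital), "died_in_hospital missing")
  bad(!is.na(raw$followup_days) & raw$followup_days < 0,
      "negative followup_days")
  bad(!is.na(raw$followup_days) & is.na(raw$event_observed),
      "followup_days present without event_observed")
  bad(!is.na(raw$event_observed) & !is.na(raw$died_in_hospital) &
        raw$died_in_hospital & !raw$event_observed,
      "died_in_hospital implies event_observed")
  if (length(problems)) {
    stop("invalid cohort file:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  class(raw) <- c("apps_cohort", class(raw))
  raw
}

parse_bool <- function(x, field) {
  if (is.logical(x)) return(x)
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0")] <- FALSE
  if (any(!is.na(x) & is.na(out))) {
    stop("column '", field, "' contains values that are not TRUE/FALSE/1/0",
         call. = FALSE)
  }
  out
}

#' Sensitivity-analysis subset: standardized ventilatory settings
#'
#' Retains exactly the patients ventilated under the standardized
#' settings PEEP >= 10 cmH2O and FiO2 >= 50 %.  Records missing either
#' value are excluded and counted.  The FiO2 unit must be declared:
#' `"percent"` (file-format default, 0--100) or `"fraction"` (0--1;
#' values are compared against 0.5).  No unit auto-detection is
#' attempted — silent unit guessing is a classic clinical-data bug.
#'
#' @param cohort data.frame with `peep` and `fio2` columns.
#' @param fio2_unit `"percent"` or `"fraction"`.
#' @return the retained subset; attribute `n_excluded_missing` counts
#'   records dropped for missing PEEP/FiO2.
#' @export
sensitivity_subset <- function(cohort, fio2_unit = c("percent", "fraction")) {
  fio2_unit <- match.arg(fio2_unit)
  stopifnot(is.data.frame(cohort))
  if (!all(c("peep", "fio2") %in% names(cohort))) {
    stop("sensitivity subset needs 'peep' and 'fio2' columns",
         call. = FALSE)
  }
  fio2_cut <- if (fio2_unit == "percent") 50 else 0.5
  has <- !is.na(cohort$peep) & !is.na(cohort$fio2)
  keep <- has & cohort$peep >= 10 & cohort$fio2 >= fio2_cut
  out <- cohort[keep, , drop = FALSE]
  attr(out, "n_excluded_missing") <- sum(!has)
  out
}
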