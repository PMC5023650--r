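#' Kaplan-Meier curve for one stratum
#'
#' Product-limit estimate of survival over follow-up, computed via
#' [survival::survfit()].  Events precede censorings at tied times (the
#' standard convention).  The returned curve starts at `S(0) = 1`.
#'
#' @param times nonnegative follow-up times (days).
#' @param events logical; `TRUE` = death observed, `FALSE` = censored.
#' @param label stratum label.
#' @return object of class `apps_km`: data.frame with columns `time`,
#'   `survival`, `at_risk`, `n_event`, plus attributes `label` and `n`.
#' @export
km_estimate <- function(times, events, label = "") {
  if (length(times) == 0) stop("empty stratum", call. = FALSE)
  if (length(times) != length(events)) {
    stop("'times' and 'events' must have equal length", call. = FALSE)
  }
  if (any(is.na(times)) || any(times < 0)) {
    stop("'times' must be nonnegative and non-missing", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    survival = c(1, fit$surv),
                    at_risk = c(length(times), fit$n.risk),
                    n_event = c(0, fit$n.event))
  structure(out, label = label, n = length(times),
            class = c("apps_km", class(out)))
}

#' Log-rank comparison of survival across strata
#'
#' Standard (unweighted) log-rank chi-square over k strata with
#' `df = k - 1`, via [survival::survdiff()].
#'
#' @param strata named list; each element a list/data.frame with
#'   components `times` and `events`.
#' @return list of class `apps_logrank` with `statistic`, `df`, `p`,
#'   `n` (per-stratum sizes).
#' @export
logrank <- function(strata) {
  stopifnot(is.list(strata), length(strata) >= 2)
  sizes <- vapply(strata, function(s) length(s$times), integer(1))
  if (any(sizes == 0)) {
    stop("stratum with zero subjects: ",
         paste(names(strata)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    time = unlist(lapply(strata, `[[`, "times")),
    event = unlist(lapply(strata, function(s) as.logical(s$events))),
    group = rep(names(strata), sizes))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(strata)
  structure(list(statistic = unname(sd$chisq), df = k - 1L,
                 p = stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE),
                 n = sizes),
            class = "apps_logrank")
}

#' @export
print.apps_logrank <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square %.3f, df %d, p %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Partition a scored cohort into score categories
#'
#' Splits patients by total score into labelled categories, e.g. the
#' original grouping 3-4 / 5-7 / 8-9 or the regrouping 3 / 4-7 / 8-9
#' that separates survival curves after recalibration.  The edges must
#' partition \{3, ..., 9\}: ordered, non-overlapping, jointly exhaustive.
#' Empty categories are kept and flagged.
#'
#' @param scored an `apps_scored` cohort with follow-up columns
#'   (`followup_days`, `event_observed`) if survival analysis follows.
#' @param category_edges list of integer vectors of score values, e.g.
#'   `list(3:4, 5:7, 8:9)`.
#' @return named list (labels like `"3-4"`) of data.frames (subsets of
#'   `scored`); attribute `empty` names empty categories.
#' @export
stratify_by_category <- function(scored, category_edges = list(3:4, 5:7, 8:9)) {
  stopifnot(is.data.frame(scored), "apps" %in% names(scored),
            is.list(category_edges), length(category_edges) >= 2)
  all_vals <- sort(unlist(category_edges))
  if (anyDuplicated(all_vals) || !identical(as.integer(all_vals), 3:9)) {
    stop("category edges must partition the score range 3..9 ",
         "(ordered, non-overlapping, jointly exhaustive)", call. = FALSE)
  }
  labels <- vapply(category_edges, function(e) {
    if (length(e) == 1) as.character(e) else paste0(min(e), "-", max(e))
  }, character(1))
  out <- lapply(category_edges, function(e) scored[scored$apps %in% e, ])
  names(out) <- labels
  empty <- labels[vapply(out, nrow, integer(1)) == 0]
  if (length(empty)) {
    warning("empty score categor", if (length(empty) > 1) "ies: " else "y: ",
            paste(empty, collapse = ", "))
  }
  attr(out, "empty") <- empty
  out
}

#' Kaplan-Meier curves and log-rank test over score categories
#'
#' Convenience wrapper: partitions the scored cohort with
#' [stratify_by_category()], estimates one KM curve per nonempty
#' category and runs the log-rank test across them.
#'
#' @inheritParams stratify_by_category
#' @return list with `curves` (list of `apps_km`), `logrank`
#'   (`apps_logrank`, or `NULL` if fewer than 2 nonempty categories),
#'   `empty` (labels of empty categories).
#' @export
km_by_category <- function(scored, category_edges = list(3:4, 5:7, 8:9)) {
  stopifnot(all(c("followup_days", "event_observed") %in% names(scored)))
  strata <- suppressWarnings(stratify_by_category(scored, category_edges))
  nonempty <- strata[vapply(strata, nrow, integer(1)) > 0]
  curves <- lapply(names(nonempty), function(lab) {
    km_estimate(nonempty[[lab]]$followup_days,
                nonempty[[lab]]$event_observed, label = lab)
  })
  names(curves) <- names(nonempty)
  lr <- if (length(nonempty) >= 2) {
    logrank(lapply(nonempty, function(s)
      list(times = s$followup_days, events = s$event_observed)))
  } else NULL
  list(curves = curves, logrank = lr, empty = attr(strata, "empty"))
}

#' Export KM curve data as delimited text
#'
#' Writes one row per (stratum, time) with survival and at-risk counts,
#' suitable for external plotting.
#'
#' @param curves list of `apps_km` objects (e.g. from [km_by_category()]).
#' @param path output CSV path.
#' @export
write_km_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(stratum = attr(cv, "label"), time = cv$time,
               survival = cv$survival, at_risk = cv$at_risk,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
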