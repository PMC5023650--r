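#' Run the full validation pipeline on a cohort
#'
#' For each score definition: scores the cohort, runs ROC analysis with
#' Youden cutoff and likelihood ratios, compares the score's AUC with
#' APACHE IV (paired DeLong, on patients with a non-missing APACHE IV),
#' assesses calibration (score-level Hosmer-Lemeshow), builds the three
#' per-variable stratum tables with odds ratios and trend tests, and —
#' when follow-up columns are present — estimates Kaplan-Meier curves
#' and the log-rank test across score categories.  With only one
#' outcome class the discrimination and calibration blocks are replaced
#' by documented failure entries and the rest of the report completes.
#'
#' The report is deterministic given the cohort and options, and every
#' number in it is produced by the corresponding module function (no
#' recomputation in formatting).
#'
#' @param cohort an `apps_cohort` data.frame (e.g. from [read_cohort()]
#'   or [generate_cohort()]).
#' @param definitions named list of `apps_definition`s; default the two
#'   built-ins.
#' @param category_edges named list (matching `definitions` names) of
#'   category partitions for survival strata; unmatched names fall back
#'   to `list(3:4, 5:7, 8:9)`.
#' @param seed integer recorded as provenance (the pipeline itself draws
#'   no random numbers).
#' @return object of class `apps_report`.
#' @export
run_validation <- function(cohort,
                           definitions = list(
                             original = builtin_definition("original"),
                             recalibrated = builtin_definition("recalibrated")),
                           category_edges = list(
                             original = list(3:4, 5:7, 8:9),
                             recalibrated = list(3, 4:7, 8:9)),
                           seed = NA_integer_) {
  stopifnot(is.data.frame(cohort), is.list(definitions),
            length(definitions) >= 1, !is.null(names(definitions)))
  n <- nrow(cohort)
  deaths <- sum(cohort$died_in_hospital)
  one_class <- deaths == 0 || deaths == n
  has_followup <- all(c("followup_days", "event_observed") %in% names(cohort)) &&
    !all(is.na(cohort$followup_days))
  has_apache <- "apache_iv" %in% names(cohort) &&
    any(!is.na(cohort$apache_iv))

  blocks <- lapply(names(definitions), function(nm) {
    def <- definitions[[nm]]
    scored <- score_cohort(cohort, def)
    block <- list(definition = def)
    if (one_class) {
      block$roc <- list(error = "single outcome class; ROC undefined")
      block$calibration <- list(error = "single outcome class")
      block$apache_comparison <- NULL
    } else {
      block$roc <- roc_analysis(scored$apps, scored$died_in_hospital)
      block$apache_comparison <- if (has_apache) {
        ok <- !is.na(cohort$apache_iv)
        yk <- cohort$died_in_hospital[ok]
        if (any(yk) && !all(yk)) {
          compare_auc_paired(scored$apps[ok], cohort$apache_iv[ok], yk)
        } else NULL
      } else NULL
      block$calibration <- tryCatch(calibration_table(scored),
                                    error = function(e)
                                      list(error = conditionMessage(e)))
    }
    block$strata <- lapply(
      stats::setNames(nm = c("age", "pf_ratio", "pmax")),
      function(v) stratify_cohort(scored, v, def))
    edges <- category_edges[[nm]]
    if (is.null(edges)) edges <- list(3:4, 5:7, 8:9)
    block$survival <- if (has_followup) km_by_category(scored, edges)
                      else NULL
    block
  })
  names(blocks) <- names(definitions)

  cfg <- list(definitions = lapply(definitions, function(d)
    list(name = d$name, boundary = d$boundary, cutoffs = d$cutoffs)),
    category_edges = category_edges)
  structure(list(
    cohort_summary = list(n = n, deaths = deaths,
                          mortality_pct = round(100 * deaths / n)),
    blocks = blocks,
    provenance = list(seed = seed, config_hash = config_hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("appsval")),
                      one_class = one_class)),
    class = "apps_report")
}

# md5 of the canonical serialized configuration
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.apps_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("APPS validation report: n = %d, deaths = %d (%d%%)\n",
              cs$n, cs$deaths, cs$mortality_pct))
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    cat("\n== Definition:", nm, "==\n")
    if (!is.null(b$roc$error)) {
      cat("ROC:", b$roc$error, "\n")
    } else {
      print(b$roc)
      if (!is.null(b$apache_comparison)) {
        cat(sprintf("vs APACHE IV: AUC %.2f vs %.2f, DeLong p = %.3g\n",
                    b$apache_comparison$auc_a, b$apache_comparison$auc_b,
                    b$apache_comparison$p))
      }
    }
    if (!is.null(b$calibration$error)) {
      cat("Calibration:", b$calibration$error, "\n")
    } else {
      print(b$calibration)
    }
    for (v in names(b$strata)) print(b$strata[[v]])
    if (!is.null(b$survival) && !is.null(b$survival$logrank)) {
      print(b$survival$logrank)
    }
  }
  invisible(x)
}

#' Machine-readable report
#'
#' Serializes an `apps_report` to JSON (byte-identical for identical
#' inputs).
#'
#' @param report an `apps_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "apps_report"))
  obj <- list(
    cohort_summary = report$cohort_summary,
    provenance = report$provenance,
    blocks = lapply(report$blocks, function(b) {
      list(
        definition = list(name = b$definition$name,
                          boundary = b$definition$boundary,
                          cutoffs = b$definition$cutoffs),
        roc = if (!is.null(b$roc$error)) b$roc else list(
          auc = b$roc$auc, ci95 = b$roc$auc_ci95,
          cutoff = b$roc$chosen_cutoff, sens = b$roc$sens_at_cutoff,
          spec = b$roc$spec_at_cutoff, lr_pos = b$roc$lr_pos,
          lr_neg = b$roc$lr_neg),
        apache_comparison = if (is.null(b$apache_comparison)) NULL else
          b$apache_comparison[c("auc_a", "auc_b", "diff", "p")],
        calibration = if (!is.null(b$calibration$error)) b$calibration
          else list(hl_statistic = b$calibration$hl_statistic,
                    hl_df = b$calibration$hl_df,
                    hl_p = b$calibration$hl_p,
                    groups = b$calibration$groups),
        strata = lapply(b$strata, function(s) {
          list(table = as.data.frame(s), p_trend = attr(s, "p_trend"))
        }),
        logrank = if (is.null(b$survival) || is.null(b$survival$logrank))
          NULL else unclass(b$survival$logrank))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12,
                         dataframe = "columns", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
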