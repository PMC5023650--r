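#' Score-level calibration table with Hosmer-Lemeshow test
#'
#' Observed versus expected hospital deaths per score level.  Expected
#' probabilities come from a univariate logistic regression of death on
#' the integer score fitted to the same cohort (calibration of an
#' integer score is undefined without an expected-probability model;
#' this choice is the package default and is reported in the result).
#' Groups are the distinct observed score values 3..9 (empty levels
#' dropped); `grouping = "deciles"` uses the standard deciles-of-risk
#' variant instead.  The statistic is
#' `sum (O - E)^2 / (E (1 - E/n))` over groups with `df = groups - 2`
#' and an upper-tail chi-square p-value.  With exactly two groups the
#' logistic fit is saturated, the statistic is 0 and p is 1 by
#' convention (flagged).
#'
#' @param scored an `apps_scored` cohort, or any data.frame with
#'   columns `apps` and `died_in_hospital`.
#' @param grouping `"score"` (default) or `"deciles"`.
#' @return object of class `apps_calibration`: list with `groups`
#'   (data.frame: `score`, `n`, `observed`, `expected`, `observed_pct`,
#'   `expected_pct`), `hl_statistic`, `hl_df`, `hl_p`, `model`
#'   (intercept/slope of the logistic fit), `grouping`, `saturated`.
#' @export
calibration_table <- function(scored, grouping = c("score", "deciles")) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(scored),
            all(c("apps", "died_in_hospital") %in% names(scored)))
  s <- scored$apps
  y <- as.logical(scored$died_in_hospital)
  if (anyNA(s) || anyNA(y)) stop("missing score or outcome", call. = FALSE)
  levels <- sort(unique(s))
  if (length(levels) < 2) {
    stop("need at least 2 distinct score levels", call. = FALSE)
  }

  # aggregated binomial fit == Bernoulli fit when the covariate is the score
  agg <- data.frame(score = levels,
                    n = as.integer(tabulate(factor(s, levels = levels))),
                    observed = vapply(levels, function(l) sum(y[s == l]),
                                      numeric(1)))
  fit <- stats::glm(cbind(observed, n - observed) ~ score,
                    family = stats::binomial(), data = agg)
  if (!fit$converged) {
    stop("logistic calibration model did not converge ",
         "(complete or quasi-complete separation of score and outcome)",
         call. = FALSE)
  }
  prob <- stats::plogis(stats::coef(fit)[1] + stats::coef(fit)[2] * agg$score)

  if (grouping == "score") {
    grp <- agg
    grp$expected <- grp$n * prob
  } else {
    p_i <- stats::plogis(stats::coef(fit)[1] + stats::coef(fit)[2] * s)
    dec <- cut(p_i, breaks = unique(stats::quantile(p_i, 0:10 / 10)),
               include.lowest = TRUE)
    grp <- data.frame(score = NA_real_,
                      n = as.integer(table(dec)),
                      observed = as.numeric(tapply(y, dec, sum)),
                      expected = as.numeric(tapply(p_i, dec, sum)))
  }
  grp$observed_pct <- 100 * grp$observed / grp$n
  grp$expected_pct <- 100 * grp$expected / grp$n

  denom <- grp$expected * (1 - grp$expected / grp$n)
  contrib <- ifelse(denom > 0, (grp$observed - grp$expected)^2 / denom, 0)
  stat <- sum(contrib)
  df <- nrow(grp) - 2L
  saturated <- df <= 0
  p <- if (saturated) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(groups = grp, hl_statistic = stat,
                 hl_df = max(df, 0L), hl_p = p,
                 model = c(intercept = unname(stats::coef(fit)[1]),
                           slope = unname(stats::coef(fit)[2])),
                 grouping = grouping, saturated = saturated),
            class = "apps_calibration")
}

#' @export
print.apps_calibration <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow (%s groups): chi-square %.3f, df %d, p %.4g%s\n",
    x$grouping, x$hl_statistic, x$hl_df, x$hl_p,
    if (x$saturated) " [saturated fit]" else ""))
  df <- x$groups
  df$observed_pct <- round(df$observed_pct, 1)
  df$expected <- round(df$expected, 1)
  df$expected_pct <- round(df$expected_pct, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

# hl_p and auc of a candidate scored cohort, from aggregated counts only
hl_auc_objective <- function(s, y) {
  levels <- sort(unique(s))
  if (length(levels) < 3) return(list(hl_p = -Inf, auc = NA_real_))
  n_g <- tabulate(factor(s, levels = levels))
  d_g <- vapply(levels, function(l) sum(y[s == l]), numeric(1))
  fit <- suppressWarnings(
    stats::glm(cbind(d_g, n_g - d_g) ~ levels, family = stats::binomial()))
  if (!fit$converged) return(list(hl_p = -Inf, auc = NA_real_))
  e_g <- n_g * stats::fitted(fit)
  denom <- e_g * (1 - e_g / n_g)
  stat <- sum(ifelse(denom > 0, (d_g - e_g)^2 / denom, 0))
  p <- stats::pchisq(stat, length(levels) - 2, lower.tail = FALSE)
  # AUC of the integer score from aggregated counts (half credit on ties)
  s_g <- n_g - d_g
  cum_s <- cumsum(c(0, s_g[-length(s_g)]))
  auc <- sum(d_g * cum_s + 0.5 * d_g * s_g) / (sum(d_g) * sum(s_g))
  list(hl_p = p, auc = auc)
}

#' Automated cutoff-search recalibration
#'
#' Re-derives band cutoffs for the chosen variables so that the score is
#' well calibrated on the given cohort, automating the manual
#' recalibration step of score-validation practice.  For each tuned
#' variable in turn, every ordered cutoff pair `(c1 < c2)` on a grid
#' between the variable's empirical 5th and 95th percentiles (step 1
#' year for age, 1 cmH2O for Pmax, 5 mmHg for PaO2/FiO2, plus the
#' current pair so the search can never do worse) is evaluated:
#' infeasible pairs — any band holding under `min_band_frac` of the
#' cohort, or stratum mortality decreasing in points — are rejected.
#' Among the rest, selection is lexicographic: (1) calibration adequacy —
#' the score-level Hosmer-Lemeshow p-value ([calibration_table()]) must
#' be at least `alpha_cal` and no lower than the starting pair's, so the
#' returned definition is never worse calibrated than its base; (2) the
#' AUC of the resulting total score is maximised; (3) ties go to the
#' cutoffs closest (L1) to the starting pair.  Adequacy-then-AUC rather
#' than outright p-maximisation is deliberate: once calibration is
#' acceptable the HL p-value is near-uniform noise and its argmax does
#' not identify the cutoffs, while the AUC peaks where the bands carry
#' the mortality signal.  If no pair clears the adequacy bar the best
#' available HL p is taken (which includes the starting pair, so
#' calibration still cannot degrade).
#'
#' @param cohort data.frame with predictor and outcome columns.
#' @param base_definition starting `apps_definition`.
#' @param variables variables to tune, default `c("age", "pmax")` (the
#'   PaO2/FiO2 cutoffs are left untouched by default).
#' @param min_band_frac minimum fraction of the cohort per band (0.05).
#' @param alpha_cal adequacy threshold on the HL p-value (0.05, the
#'   conventional significance level: calibration is adequate when not
#'   rejected at this level).
#' @param steps named grid steps; defaults `age = 1`, `pmax = 1`,
#'   `pf_ratio = 5`.
#' @return object of class `apps_recalibration`: list with `definition`
#'   (tuned), `base_definition`, `base_hl_p`, `achieved_hl_p`,
#'   `achieved_auc`, `search_log` (data.frame of every evaluated pair
#'   with feasibility and objective values).
#' @export
recalibrate <- function(cohort, base_definition = builtin_definition("original"),
                        variables = c("age", "pmax"),
                        min_band_frac = 0.05,
                        alpha_cal = 0.05,
                        steps = c(age = 1, pmax = 1, pf_ratio = 5)) {
  stopifnot(is.data.frame(cohort), length(variables) >= 1,
            all(variables %in% c("age", "pf_ratio", "pmax")))
  scored <- score_cohort(cohort, base_definition)
  y <- as.logical(cohort$died_in_hospital)
  n <- nrow(cohort)
  base_hl_p <- calibration_table(scored)$hl_p

  current <- base_definition
  pts <- list(age = scored$age_pts, pf_ratio = scored$pf_pts,
              pmax = scored$pmax_pts)
  logs <- list()

  for (v in variables) {
    x <- cohort[[v]]
    qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    grid <- seq(ceiling(qs[1]), floor(qs[2]), by = steps[[v]])
    pairs <- expand.grid(c1 = grid, c2 = grid)
    pairs <- pairs[pairs$c1 < pairs$c2, ]
    cur <- current$cutoffs[[v]]
    pairs <- unique(rbind(pairs, data.frame(c1 = cur[1], c2 = cur[2])))

    others <- Reduce(`+`, pts[setdiff(names(pts), v)])
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      c1 <- pairs$c1[i]; c2 <- pairs$c2[i]
      cand <- current
      cand$cutoffs[[v]] <- c(c1, c2)
      pv <- assign_points(x, v, cand)
      if (c1 == cur[1] && c2 == cur[2]) {
        # the status-quo pair is always admissible, so the search can
        # never return a worse calibration than it started from
        ob <- hl_auc_objective(pv + others, y)
        return(data.frame(variable = v, c1 = c1, c2 = c2, feasible = TRUE,
                          reason = "current", hl_p = ob$hl_p, auc = ob$auc))
      }
      sizes <- tabulate(pv, nbins = 3)
      if (any(sizes < min_band_frac * n)) {
        return(data.frame(variable = v, c1 = c1, c2 = c2, feasible = FALSE,
                          reason = "band_too_small", hl_p = NA, auc = NA))
      }
      rate <- vapply(1:3, function(c) mean(y[pv == c]), numeric(1))
      if (is.unsorted(rate)) {
        return(data.frame(variable = v, c1 = c1, c2 = c2, feasible = FALSE,
                          reason = "non_monotone_mortality", hl_p = NA,
                          auc = NA))
      }
      ob <- hl_auc_objective(pv + others, y)
      data.frame(variable = v, c1 = c1, c2 = c2, feasible = TRUE,
                 reason = "", hl_p = ob$hl_p, auc = ob$auc)
    })
    log_v <- do.call(rbind, res)
    logs[[v]] <- log_v

    feas <- log_v[log_v$feasible & is.finite(log_v$hl_p), ]
    if (sum(feas$reason != "current") == 0) {
      tab <- table(log_v$reason[!log_v$feasible])
      stop("no feasible cutoff pair for '", v, "'; binding constraint: ",
           names(tab)[which.max(tab)], call. = FALSE)
    }
    # Selection: calibration adequacy first, then discrimination.
    # Among pairs whose HL p is at least alpha_cal AND no worse than the
    # pass's starting pair (so calibration never degrades), maximise the
    # AUC of the resulting score, ties broken by cutoffs closest (L1) to
    # the starting pair.  Maximising the HL p itself beyond adequacy
    # would chase sampling noise: under good calibration the p-value is
    # near-uniform, so its argmax carries no information about the
    # cutoffs, whereas the AUC peaks at the bands that actually carry
    # the mortality signal.
    cur_hl_p <- feas$hl_p[feas$reason == "current"][1]
    cand <- feas[feas$hl_p >= max(alpha_cal, cur_hl_p), ]
    if (nrow(cand) == 0) cand <- feas[which.max(feas$hl_p), , drop = FALSE]
    dist <- abs(cand$c1 - cur[1]) + abs(cand$c2 - cur[2])
    ord <- order(-cand$auc, dist, cand$c1, cand$c2)
    best <- cand[ord[1], ]
    current$cutoffs[[v]] <- c(best$c1, best$c2)
    pts[[v]] <- assign_points(x, v, current)
  }

  current$name <- paste0(base_definition$name, "_recalibrated")
  final <- calibration_table(score_cohort(cohort, current))
  structure(list(definition = current,
                 base_definition = base_definition,
                 base_hl_p = base_hl_p,
                 achieved_hl_p = final$hl_p,
                 achieved_auc = hl_auc_objective(
                   Reduce(`+`, pts), y)$auc,
                 search_log = do.call(rbind, logs)),
            class = "apps_recalibration")
}

#' @export
print.apps_recalibration <- function(x, ...) {
  cat("Recalibration of '", x$base_definition$name, "'\n", sep = "")
  for (v in unique(x$search_log$variable)) {
    cat(sprintf("  %-9s %s -> %s\n", v,
                paste(x$base_definition$cutoffs[[v]], collapse = "/"),
                paste(x$definition$cutoffs[[v]], collapse = "/")))
  }
  cat(sprintf("  HL p: %.4g -> %.4g  (%d cutoff pairs evaluated)\n",
              x$base_hl_p, x$achieved_hl_p, nrow(x$search_log)))
  invisible(x)
}
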