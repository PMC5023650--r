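#' AUC with confidence interval
#'
#' The area under the ROC curve is computed as the tie-corrected
#' pairwise concordance probability
#' `P(score_death > score_survivor) + 0.5 P(equal)` via the
#' Mann–Whitney midrank identity.  The default 95 % interval uses the
#' DeLong structural-components variance: with placement values
#' `V10_i` (for each death, the fraction of survivors scored below it,
#' ties counting one half) and `V01_j` (symmetrically for survivors),
#' `var(AUC) = var(V10)/m + var(V01)/n`, and the interval is
#' `AUC +/- z * SE` clipped to \[0, 1\] on the probability scale.
#' `ci = "bootstrap"` substitutes a stratified nonparametric bootstrap
#' percentile interval.
#'
#' @param scores numeric predictor values (higher = more likely to die).
#' @param outcomes logical (or 0/1) hospital-death indicator.
#' @param ci `"delong"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap resamples when `ci = "bootstrap"`.
#' @param conf confidence level.
#' @return list with `auc`, `ci95 = c(lower, upper)`, `se`, `m` (deaths),
#'   `n` (survivors), `ci_method`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc  # 1
#' @export
roc_auc <- function(scores, outcomes, ci = c("delong", "bootstrap"),
                    boot_n = 2000, conf = 0.95) {
  ci <- match.arg(ci)
  chk <- check_roc_input(scores, outcomes)
  comp <- delong_components(chk$scores, chk$outcomes)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (ci == "delong") {
    se <- sqrt(comp$var)
    bounds <- pmin(pmax(comp$auc + c(-1, 1) * z * se, 0), 1)
  } else {
    se <- sqrt(comp$var)
    bounds <- boot_auc_ci(chk$scores, chk$outcomes, boot_n, conf)
  }
  list(auc = comp$auc, ci95 = bounds, se = se,
       m = comp$m, n = comp$n, ci_method = ci)
}

check_roc_input <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) {
    stop("'scores' and 'outcomes' must have equal length", call. = FALSE)
  }
  outcomes <- as.logical(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  if (!any(outcomes) || all(outcomes)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  list(scores = scores, outcomes = outcomes)
}

# Midrank placement values a la DeLong: O(N log N).
delong_components <- function(scores, outcomes) {
  x <- scores[outcomes]    # deaths
  y <- scores[!outcomes]   # survivors
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n          # per-death placements
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m  # per-survivor placements
  auc <- mean(v10)  # == mean(v01)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  list(auc = auc, v10 = v10, v01 = v01, var = s10 / m + s01 / n,
       m = m, n = n)
}

boot_auc_ci <- function(scores, outcomes, boot_n, conf) {
  idx1 <- which(outcomes); idx0 <- which(!outcomes)
  stat <- vapply(seq_len(boot_n), function(b) {
    i <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
    delong_components(scores[i], outcomes[i])$auc
  }, numeric(1))
  unname(stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         type = 7))
}

#' Paired DeLong comparison of two AUCs
#'
#' Tests whether two scores measured on the *same* patients have equal
#' AUC for the same outcome, using the DeLong paired structural
#' components: the variance of the AUC difference subtracts twice the
#' covariance of the placement values, and the z statistic is referred
#' to the standard normal (two-sided).  When both scores rank the
#' patients identically the difference and its variance are both zero;
#' p is then 1 by convention.
#'
#' @param scores_a,scores_b numeric vectors, same patients.
#' @param outcomes logical hospital-death indicator.
#' @return list with `auc_a`, `auc_b`, `diff`, `se_diff`, `z`, `p`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, outcomes) {
  if (length(scores_a) != length(scores_b)) {
    stop("'scores_a' and 'scores_b' must have equal length", call. = FALSE)
  }
  outcomes <- as.logical(outcomes)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(outcomes)
  a <- scores_a[keep]; b <- scores_b[keep]; y <- outcomes[keep]
  if (!any(y) || all(y)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  ca <- delong_components(a, y)
  cb <- delong_components(b, y)
  m <- ca$m; n <- ca$n
  cov10 <- if (m > 1) stats::cov(ca$v10, cb$v10) else 0
  cov01 <- if (n > 1) stats::cov(ca$v01, cb$v01) else 0
  var_diff <- ca$var + cb$var - 2 * (cov10 / m + cov01 / n)
  diff <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, diff = diff,
       se_diff = sqrt(max(var_diff, 0)), z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Full ROC analysis with Youden-optimal cutoff
#'
#' Builds the ROC step function over candidate cutoffs at the midpoints
#' between adjacent distinct score values ("positive" = score strictly
#' above the cutoff, so the integer-score cutoff 5.5 means a positive
#' test at a score of 6 or more), computes the AUC with its interval
#' via [roc_auc()], and selects the cutoff maximising the Youden index
#' `J = sens + spec - 1`, ties broken toward the lower cutoff.
#' Likelihood ratios at the chosen cutoff are
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`.
#'
#' @inheritParams roc_auc
#' @return object of class `apps_roc`: list with `thresholds`, `sens`,
#'   `spec` (per threshold), `auc`, `auc_ci95`, `chosen_cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `youden`, `lr_pos`, `lr_neg`,
#'   `all_tied` flag.
#' @examples
#' ra <- roc_analysis(c(3, 4, 6, 7), c(FALSE, FALSE, TRUE, TRUE))
#' ra$chosen_cutoff  # 5
#' @export
roc_analysis <- function(scores, outcomes, ci = "delong") {
  chk <- check_roc_input(scores, outcomes)
  scores <- chk$scores; outcomes <- chk$outcomes
  u <- sort(unique(scores))
  all_tied <- length(u) == 1L
  thr <- if (all_tied) u else (u[-length(u)] + u[-1]) / 2
  m <- sum(outcomes); n <- sum(!outcomes)
  f <- factor(scores, levels = u)
  cd <- cumsum(tabulate(f[outcomes], nbins = length(u)))
  cs <- cumsum(tabulate(f[!outcomes], nbins = length(u)))
  # threshold i sits between u[i] and u[i+1]: positive <=> score >= u[i+1]
  k <- seq_along(thr)
  sens <- (m - cd[k]) / m
  spec <- cs[k] / n
  j <- sens + spec - 1
  best <- which.max(j)  # first max = lowest cutoff on ties
  aucr <- roc_auc(scores, outcomes, ci = ci)
  lr <- likelihood_ratios(sens[best], spec[best])
  structure(list(thresholds = thr, sens = sens, spec = spec,
                 auc = aucr$auc, auc_ci95 = aucr$ci95,
                 chosen_cutoff = thr[best],
                 sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
                 youden = j[best], lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
                 all_tied = all_tied, ci_method = aucr$ci_method),
            class = "apps_roc")
}

#' @export
print.apps_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.2f (95%% CI %.2f-%.2f, %s)\n", x$auc, x$auc_ci95[1],
    x$auc_ci95[2], x$ci_method))
  cat(sprintf(
    "Youden cutoff %.1f: sens %.2f, spec %.2f, LR+ %.2f, LR- %.2f%s\n",
    x$chosen_cutoff, x$sens_at_cutoff, x$spec_at_cutoff, x$lr_pos,
    x$lr_neg, if (x$all_tied) "  [all scores tied]" else ""))
  invisible(x)
}

#' Youden-optimal cutoff of an existing ROC analysis
#'
#' @param roc an `apps_roc` from [roc_analysis()].
#' @return list with `cutoff`, `sens`, `spec`, `youden`, `lr_pos`,
#'   `lr_neg`, `all_tied`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "apps_roc"))
  list(cutoff = roc$chosen_cutoff, sens = roc$sens_at_cutoff,
       spec = roc$spec_at_cutoff, youden = roc$youden,
       lr_pos = roc$lr_pos, lr_neg = roc$lr_neg, all_tied = roc$all_tied)
}

#' Likelihood ratios from sensitivity and specificity
#'
#' @param sens,spec proportions in \[0, 1\].
#' @return list with `lr_pos = sens/(1-spec)` and
#'   `lr_neg = (1-sens)/spec` (`Inf` on zero denominators).
#' @examples
#' likelihood_ratios(0.63, 0.56)  # LR+ 1.43, LR- 0.66
#' @export
likelihood_ratios <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  list(lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
       lr_neg = if (spec > 0) (1 - sens) / spec else Inf)
}
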