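#' Logistic mortality mechanism for synthetic cohorts
#'
#' Hospital death is simulated from a logistic model on the score's
#' component points: `logit P(death) = intercept + b_age[age_pts] +
#' b_pf[pf_pts] + b_pmax[pmax_pts]`.  Two parameterisations are
#' supported:
#' \itemize{
#'   \item a single per-point slope (`slope`), in which case
#'     `b_v[c] = slope * c` and the linear predictor collapses to
#'     `intercept + slope * total_score`;
#'   \item explicit per-band log-odds offsets (`offsets`), one numeric
#'     triple per variable with the 1-point band as reference (first
#'     element 0).  This is what [calibrate_spec_to_margins()] fits,
#'     since published stratum death rates are generally not linear on
#'     the log-odds scale in the band index.
#' }
#'
#' @param intercept log-odds intercept.
#' @param slope per-point log-odds slope (ignored when `offsets` given).
#' @param offsets optional named list `age`/`pf_ratio`/`pmax` of numeric
#'   triples of per-band log-odds offsets.
#' @return object of class `apps_mortality_model`.
#' @export
mortality_model <- function(intercept, slope = 0, offsets = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  vars <- c("age", "pf_ratio", "pmax")
  if (is.null(offsets)) {
    stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
    coefs <- stats::setNames(rep(list(slope * (1:3)), 3), vars)
  } else {
    if (!is.list(offsets) || !all(names(offsets) %in% vars)) {
      stop("'offsets' must be a named list over ",
           paste(vars, collapse = ", "), call. = FALSE)
    }
    coefs <- stats::setNames(rep(list(c(0, 0, 0)), 3), vars)
    for (v in names(offsets)) {
      ov <- offsets[[v]]
      if (!is.numeric(ov) || length(ov) != 3L || anyNA(ov)) {
        stop("offsets for '", v, "' must be three finite numbers",
             call. = FALSE)
      }
      coefs[[v]] <- as.numeric(ov)
    }
    slope <- NA_real_
  }
  structure(list(intercept = intercept, slope = slope, coef = coefs),
            class = "apps_mortality_model")
}

death_linpred <- function(model, age_pts, pf_pts, pmax_pts) {
  model$intercept + model$coef$age[age_pts] + model$coef$pf_ratio[pf_pts] +
    model$coef$pmax[pmax_pts]
}

#' Synthetic ARDS cohort specification
#'
#' Bundles everything needed to simulate a moderate/severe ARDS cohort:
#' predictor marginals, the mortality mechanism, follow-up horizon and
#' the seed.  Defaults emulate the validation cohort the package's
#' worked examples are built around: age 58.5 +/- 15.4 y in survivors vs
#' 63.1 +/- 12.7 y in non-survivors, PaO2/FiO2 127 +/- 40 mmHg, maximal
#' airway pressure 27 +/- 8.5 cmH2O, 43 % overall hospital mortality and
#' a per-point log-odds slope of 0.4 (odds ratio about 1.5 per score
#' point, the magnitude of the published per-category odds ratios).
#'
#' Predictors are drawn as independent truncated normals (age 18--100 y,
#' PaO2/FiO2 30--200 mmHg so every patient meets the moderate/severe
#' entry criterion PaO2/FiO2 <= 200, Pmax 10--50 cmH2O); mortality is
#' induced only through the score, so the per-arm age parameters are
#' pooled (weighted by the overall mortality target) into marginal
#' moments before drawing.
#'
#' @param n_patients number of patients (>= 1).
#' @param age_params list with `survivor` and `nonsurvivor`, each
#'   `c(mean, sd)` in years.
#' @param pf_params `c(mean, sd)` of PaO2/FiO2 in mmHg.
#' @param pmax_params `c(mean, sd)` of maximal airway pressure in cmH2O.
#' @param mortality an [mortality_model()].
#' @param overall_mortality_target proportion in (0,1) or `NULL`.  When
#'   given, the model intercept is re-solved at generation time so the
#'   expected cohort mortality equals the target (the slope/offsets are
#'   kept); when `NULL` the intercept is used as-is.
#' @param seed integer seed controlling all draws.
#' @param followup_horizon days; deaths occur within `(0, horizon]`,
#'   survivors are censored at a log-normal discharge time capped at the
#'   horizon.
#' @param definition `apps_definition` used as the *true* score inside
#'   the mortality mechanism.
#' @return object of class `apps_cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_patients = 439, seed = 1)
#' co <- generate_cohort(spec)
#' mean(co$died_in_hospital)
#' @export
cohort_spec <- function(n_patients = 439,
                        age_params = list(survivor = c(mean = 58.5, sd = 15.4),
                                          nonsurvivor = c(mean = 63.1, sd = 12.7)),
                        pf_params = c(mean = 127, sd = 40),
                        pmax_params = c(mean = 27, sd = 8.5),
                        mortality = mortality_model(stats::qlogis(0.43),
                                                    slope = 0.4),
                        overall_mortality_target = 0.43,
                        seed = 1L,
                        followup_horizon = 60,
                        definition = builtin_definition("original")) {
  fail <- function(field, why) {
    stop("invalid cohort spec: field '", field, "' ", why, call. = FALSE)
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1 || n_patients != floor(n_patients)) {
    fail("n_patients", "must be a positive integer")
  }
  chk_ms <- function(x, field) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x)) {
      fail(field, "must be c(mean, sd)")
    }
    if (x[2] <= 0) fail(field, "must have sd > 0")
  }
  if (!is.list(age_params) ||
      !all(c("survivor", "nonsurvivor") %in% names(age_params))) {
    fail("age_params", "must list 'survivor' and 'nonsurvivor' arms")
  }
  chk_ms(age_params$survivor, "age_params$survivor")
  chk_ms(age_params$nonsurvivor, "age_params$nonsurvivor")
  chk_ms(pf_params, "pf_params")
  chk_ms(pmax_params, "pmax_params")
  if (!inherits(mortality, "apps_mortality_model")) {
    fail("mortality", "must be a mortality_model()")
  }
  if (!is.null(overall_mortality_target)) {
    t <- overall_mortality_target
    if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t >= 1) {
      fail("overall_mortality_target", "must lie in (0, 1)")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    fail("seed", "must be a single integer")
  }
  if (!is.numeric(followup_horizon) || length(followup_horizon) != 1L ||
      is.na(followup_horizon) || followup_horizon <= 0) {
    fail("followup_horizon", "must be a positive number of days")
  }
  if (!inherits(definition, "apps_definition")) {
    fail("definition", "must be an apps_definition")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         age_params = age_params,
         pf_params = c(mean = unname(pf_params[1]), sd = unname(pf_params[2])),
         pmax_params = c(mean = unname(pmax_params[1]),
                         sd = unname(pmax_params[2])),
         mortality = mortality,
         overall_mortality_target = overall_mortality_target,
         seed = as.integer(seed),
         followup_horizon = followup_horizon,
         definition = definition,
         # fixed physiological truncation bounds
         bounds = list(age = c(18, 100), pf_ratio = c(30, 200),
                       pmax = c(10, 50))),
    class = "apps_cohort_spec")
}

# inverse-CDF truncated normal; deterministic given the runif stream
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# P(band = 1,2,3) for one variable under its truncated normal marginal.
# Continuous marginals make the boundary convention measure-zero here.
band_probs <- function(cuts, mean, sd, bounds, decreasing = FALSE) {
  ftr <- function(t) {
    (stats::pnorm(t, mean, sd) - stats::pnorm(bounds[1], mean, sd)) /
      (stats::pnorm(bounds[2], mean, sd) - stats::pnorm(bounds[1], mean, sd))
  }
  t1 <- max(min(ftr(cuts[1]), 1), 0)
  t2 <- max(min(ftr(cuts[2]), 1), 0)
  p <- c(t1, t2 - t1, 1 - t2)          # below cut1 / between / above cut2
  if (decreasing) rev(p) else p        # pf_ratio: 3 points below cut1
}

# pooled marginal age moments from the per-arm parameters
pooled_age <- function(spec) {
  p <- if (is.null(spec$overall_mortality_target)) 0.43
       else spec$overall_mortality_target
  s <- spec$age_params$survivor; d <- spec$age_params$nonsurvivor
  m <- (1 - p) * s[1] + p * d[1]
  v <- (1 - p) * (s[2]^2 + s[1]^2) + p * (d[2]^2 + d[1]^2) - m^2
  c(mean = unname(m), sd = sqrt(unname(v)))
}

# per-variable band probabilities under the spec's marginals
spec_band_probs <- function(spec) {
  ag <- pooled_age(spec)
  list(
    age = band_probs(spec$definition$cutoffs$age, ag[1], ag[2],
                     spec$bounds$age),
    pf_ratio = band_probs(spec$definition$cutoffs$pf_ratio,
                          spec$pf_params[1], spec$pf_params[2],
                          spec$bounds$pf_ratio, decreasing = TRUE),
    pmax = band_probs(spec$definition$cutoffs$pmax,
                      spec$pmax_params[1], spec$pmax_params[2],
                      spec$bounds$pmax))
}

# expected cohort mortality given intercept a, exact over the 27 point cells
expected_mortality <- function(a, model, probs) {
  cells <- expand.grid(age = 1:3, pf = 1:3, pmax = 1:3)
  w <- probs$age[cells$age] * probs$pf_ratio[cells$pf] * probs$pmax[cells$pmax]
  lp <- model$coef$age[cells$age] + model$coef$pf_ratio[cells$pf] +
    model$coef$pmax[cells$pmax]
  sum(w * stats::plogis(a + lp))
}

# intercept meeting the overall mortality target (slope/offsets fixed)
solve_intercept <- function(model, probs, target) {
  stats::uniroot(function(a) expected_mortality(a, model, probs) - target,
                 interval = c(-30, 30), tol = 1e-10)$root
}

# effective model after applying the overall mortality target, if any
effective_model <- function(spec) {
  model <- spec$mortality
  if (!is.null(spec$overall_mortality_target)) {
    probs <- spec_band_probs(spec)
    model$intercept <- solve_intercept(model, probs,
                                       spec$overall_mortality_target)
  }
  model
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` records under the spec.  Draw order is fixed and
#' documented so that a given `(spec, seed)` pair is reproducible across
#' versions: (1) age, (2) PaO2/FiO2, (3) Pmax — each by inverse-CDF
#' truncated normal sampling — then (4) the death uniform, (5) the death
#' time uniform, (6) the log-normal discharge time, (7) APACHE IV,
#' (8) PEEP, (9) FiO2.  APACHE IV, PEEP and FiO2 are drawn conditional
#' on the simulated outcome arm (truncated normals with arm-specific
#' moments) so the comparator score and the sensitivity-analysis filter
#' behave realistically; they feed back into nothing.
#'
#' @param spec an [cohort_spec()].
#' @return data.frame of class `apps_cohort` with columns `id`, `age`,
#'   `pf_ratio`, `pmax`, `died_in_hospital`, `apache_iv`,
#'   `followup_days`, `event_observed`, `peep`, `fio2`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "apps_cohort_spec")) {
    stop("'spec' must be created by cohort_spec()", call. = FALSE)
  }
  n <- spec$n_patients
  model <- effective_model(spec)
  ag <- pooled_age(spec)

  set.seed(spec$seed)
  age  <- rtruncnorm(n, ag[1], ag[2], spec$bounds$age[1], spec$bounds$age[2])
  pf   <- rtruncnorm(n, spec$pf_params[1], spec$pf_params[2],
                     spec$bounds$pf_ratio[1], spec$bounds$pf_ratio[2])
  pmax <- rtruncnorm(n, spec$pmax_params[1], spec$pmax_params[2],
                     spec$bounds$pmax[1], spec$bounds$pmax[2])

  a_pts <- assign_points(age, "age", spec$definition)
  f_pts <- assign_points(pf, "pf_ratio", spec$definition)
  m_pts <- assign_points(pmax, "pmax", spec$definition)
  p_death <- stats::plogis(death_linpred(model, a_pts, f_pts, m_pts))
  died <- stats::runif(n) < p_death

  horizon <- spec$followup_horizon
  t_death <- horizon * (1 - stats::runif(n))        # uniform on (0, horizon]
  t_disch <- pmin(stats::rlnorm(n, log(15), 0.5), horizon)
  followup <- ifelse(died, t_death, t_disch)

  apache <- rtruncnorm(n, ifelse(died, 102.7, 85.5),
                       ifelse(died, 30.7, 27), 0, 250)
  peep   <- rtruncnorm(n, ifelse(died, 10.9, 10.4),
                       ifelse(died, 4, 3.6), 0, 30)
  fio2   <- rtruncnorm(n, ifelse(died, 56.7, 53.2),
                       ifelse(died, 16.7, 12.9), 21, 100)

  out <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = age, pf_ratio = pf, pmax = pmax,
    died_in_hospital = died,
    apache_iv = apache,
    followup_days = followup,
    event_observed = died,
    peep = peep, fio2 = fio2,
    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  class(out) <- c("apps_cohort", class(out))
  out
}

#' Calibrate a cohort spec to target stratum death rates
#'
#' Finds a mortality mechanism whose large-sample cohorts reproduce the
#' given per-band death proportions.  For each targeted variable the
#' three band rates are matched by fitting a shared intercept and
#' per-band log-odds offsets (1-point band as reference) by least
#' squares on the *analytic* stratum rates — under independent
#' predictors the rate in band `c` of variable `v` is an exact
#' probability-weighted average of `plogis` over the other variables'
#' band cells, so no simulation is needed during the search.  With a
#' single targeted variable the solution is closed-form; with all three
#' it is a 7-parameter least-squares fit over 9 targets.
#'
#' @param targets named list over a subset of `age`, `pf_ratio`, `pmax`;
#'   each element a numeric triple of death proportions in (0,1), ordered
#'   by band points 1, 2, 3.
#' @param base_spec spec supplying marginals, seed, definition; its
#'   mortality model and overall-mortality target are replaced.
#' @param tol maximum absolute deviation (proportion) allowed between
#'   the analytic stratum rates of the fitted mechanism and the targets;
#'   exceeding it raises an infeasibility error.
#' @return an `apps_cohort_spec` whose `"calibration"` attribute records
#'   the search method, targets, analytically achieved rates and fitted
#'   offsets.
#' @examples
#' sp <- calibrate_spec_to_margins(list(age = c(0.264, 0.439, 0.480)))
#' attr(sp, "calibration")$achieved$age
#' @export
calibrate_spec_to_margins <- function(targets,
                                      base_spec = cohort_spec(),
                                      tol = 0.03) {
  vars <- c("age", "pf_ratio", "pmax")
  if (!is.list(targets) || length(targets) == 0 ||
      !all(names(targets) %in% vars)) {
    stop("'targets' must be a named list over a subset of ",
         paste(vars, collapse = ", "), call. = FALSE)
  }
  for (v in names(targets)) {
    tv <- targets[[v]]
    if (!is.numeric(tv) || length(tv) != 3L || anyNA(tv) ||
        any(tv <= 0) || any(tv >= 1)) {
      stop("targets for '", v, "' must be three proportions in (0, 1)",
           call. = FALSE)
    }
  }
  probs <- spec_band_probs(base_spec)
  tuned <- names(targets)

  # analytic band rates for the targeted variables given parameters
  # theta = (intercept, then offsets 2 and 3 for each tuned variable)
  unpack <- function(theta) {
    off <- stats::setNames(rep(list(c(0, 0, 0)), 3), vars)
    k <- 1L
    for (v in tuned) {
      off[[v]] <- c(0, theta[k + 1L], theta[k + 2L])
      k <- k + 2L
    }
    list(a = theta[1L], off = off)
  }
  rates <- function(theta) {
    par <- unpack(theta)
    out <- list()
    for (v in tuned) {
      others <- setdiff(vars, v)
      cells <- expand.grid(u = 1:3, w = 1:3)
      wgt <- probs[[others[1]]][cells$u] * probs[[others[2]]][cells$w]
      lp_others <- par$off[[others[1]]][cells$u] +
        par$off[[others[2]]][cells$w]
      out[[v]] <- vapply(1:3, function(c) {
        sum(wgt * stats::plogis(par$a + par$off[[v]][c] + lp_others))
      }, numeric(1))
    }
    out
  }
  tvec <- unlist(targets[tuned])
  obj <- function(theta) sum((unlist(rates(theta)) - tvec)^2)

  lt <- stats::qlogis(targets[[tuned[1]]])
  init <- c(lt[1],
            unlist(lapply(tuned, function(v) {
              lv <- stats::qlogis(targets[[v]])
              lv[2:3] - lv[1]
            })))
  fit <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  achieved <- rates(fit$par)
  dev <- max(abs(unlist(achieved) - tvec))
  if (dev > tol) {
    stop("infeasible margin targets: best fit deviates by ",
         sprintf("%.4f", dev), " (> tol = ", tol, ") from the targets; ",
         "targets may be incompatible with the spec's predictor marginals",
         call. = FALSE)
  }
  par <- unpack(fit$par)
  model <- mortality_model(par$a, offsets = par$off)
  spec <- base_spec
  spec$mortality <- model
  spec$overall_mortality_target <- NULL
  attr(spec, "calibration") <- list(
    method = paste("least squares on analytic stratum rates",
                   "(BFGS over intercept + per-band offsets)"),
    targets = targets, achieved = achieved,
    offsets = par$off[tuned], max_abs_deviation = dev,
    converged = fit$convergence == 0)
  spec
}

#' Read / write a cohort spec as a structured config file
#'
#' The spec is serialized as nested YAML (predictor marginals, mortality
#' coefficients, seed, horizon, and the score definition inline).
#'
#' @param spec an `apps_cohort_spec`.
#' @param path file path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "apps_cohort_spec"))
  obj <- list(
    n_patients = spec$n_patients,
    age_params = lapply(spec$age_params, function(x)
      list(mean = unname(x[1]), sd = unname(x[2]))),
    pf_params = list(mean = unname(spec$pf_params[1]),
                     sd = unname(spec$pf_params[2])),
    pmax_params = list(mean = unname(spec$pmax_params[1]),
                       sd = unname(spec$pmax_params[2])),
    mortality = list(intercept = spec$mortality$intercept,
                     coef = spec$mortality$coef),
    overall_mortality_target = spec$overall_mortality_target,
    seed = spec$seed,
    followup_horizon = spec$followup_horizon,
    definition = list(name = spec$definition$name,
                      boundary = spec$definition$boundary,
                      cutoffs = spec$definition$cutoffs))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  o <- yaml::read_yaml(path)
  model <- mortality_model(o$mortality$intercept,
                           offsets = lapply(o$mortality$coef, function(b) {
                             b <- as.numeric(b); b  # stored as-is
                           }))
  # offsets are stored unnormalised; restore verbatim
  model$coef <- lapply(o$mortality$coef, as.numeric)
  cohort_spec(
    n_patients = o$n_patients,
    age_params = list(
      survivor = c(mean = o$age_params$survivor$mean,
                   sd = o$age_params$survivor$sd),
      nonsurvivor = c(mean = o$age_params$nonsurvivor$mean,
                      sd = o$age_params$nonsurvivor$sd)),
    pf_params = c(mean = o$pf_params$mean, sd = o$pf_params$sd),
    pmax_params = c(mean = o$pmax_params$mean, sd = o$pmax_params$sd),
    mortality = model,
    overall_mortality_target = o$overall_mortality_target,
    seed = o$seed,
    followup_horizon = o$followup_horizon,
    definition = score_definition(o$definition$name,
                                  lapply(o$definition$cutoffs, as.numeric),
                                  boundary = o$definition$boundary))
}
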