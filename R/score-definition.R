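#' Cutoff-table score definitions
#'
#' An `apps_definition` describes a three-variable additive point score.
#' Each variable (`age` in years, `pf_ratio` in mmHg, `pmax` in cmH2O)
#' is split into three ordered bands worth 1, 2 and 3 points; the total
#' score is the sum over the three variables and therefore lies in 3..9.
#' Risk direction is fixed by physiology: higher age and higher maximal
#' airway pressure score more points, while a *lower* PaO2/FiO2 ratio
#' scores more points.
#'
#' A definition stores, per variable, the two interior cutoffs
#' `(cut1, cut2)` with `cut1 < cut2` and a boundary convention.  Under
#' the default `"closed"` convention the printed dash-range `[cut1, cut2]`
#' is the 2-point band (for `pf_ratio`, mirrored on the risk direction),
#' so e.g. age bands are `(-Inf, cut1)`, `[cut1, cut2]`, `(cut2, Inf)`.
#' The alternative `"open"` convention shifts band membership at the
#' boundary itself: age bands become `(-Inf, cut1]`, `(cut1, cut2]`,
#' `(cut2, Inf)`.  Exact boundary membership is rarely stated in score
#' publications, so the convention is part of the definition file.
#'
#' @param name character; a label for the definition.
#' @param cutoffs named list with elements `age`, `pf_ratio`, `pmax`,
#'   each a numeric vector `c(cut1, cut2)` with `cut1 < cut2`.
#' @param boundary `"closed"` (default) or `"open"`; see Details.
#' @return An object of class `apps_definition`.
#' @examples
#' d <- score_definition("demo",
#'   cutoffs = list(age = c(47, 66), pf_ratio = c(105, 158),
#'                  pmax = c(27, 30)))
#' band_table(d)
#' @seealso [builtin_definition()], [score_cohort()], [band_table()]
#' @export
score_definition <- function(name, cutoffs, boundary = c("closed", "open")) {
  boundary <- match.arg(boundary)
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("'name' must be a single string", call. = FALSE)
  }
  need <- c("age", "pf_ratio", "pmax")
  if (!is.list(cutoffs) || !all(need %in% names(cutoffs))) {
    stop("'cutoffs' must be a named list with elements ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (v in need) {
    cv <- cutoffs[[v]]
    if (!is.numeric(cv) || length(cv) != 2L || anyNA(cv) || cv[1] >= cv[2]) {
      stop("cutoffs for '", v, "' must be two finite numbers with cut1 < cut2",
           call. = FALSE)
    }
  }
  structure(
    list(name = name,
         cutoffs = lapply(cutoffs[need], as.numeric),
         boundary = boundary),
    class = "apps_definition")
}

#' Built-in APPS cutoff sets
#'
#' Returns one of the packaged score definitions:
#' \describe{
#'   \item{`original`}{age <47 / 47--66 / >66; PaO2/FiO2 >158 / 105--158 /
#'     <105; Pmax <27 / 27--30 / >30.}
#'   \item{`recalibrated`}{age <47 / 47--59 / >59; PaO2/FiO2 unchanged;
#'     Pmax <30 / 30--33 / >33.}
#'   \item{`original_printed`}{a variant of `original` whose Pmax 2-point
#'     band is widened to 27--33.  Published stratum tables for the
#'     original score sometimes tabulate the top Pmax band as >33 while
#'     leaving 30--33 unassigned (the printed stratum sizes then sum to
#'     fewer patients than the cohort); since score bands must be
#'     exhaustive, this variant absorbs the gap into the middle band so
#'     the outer bands match the tabulation.  Use it only to mirror such
#'     tables; `original` is the score as defined.}
#' }
#'
#' Definitions are read from the YAML files shipped under
#' `inst/extdata/definitions/` and cached for the session.
#'
#' @param which one of `"original"`, `"recalibrated"`, `"original_printed"`.
#' @return An `apps_definition`.
#' @examples
#' builtin_definition("original")
#' @export
builtin_definition <- function(which = c("original", "recalibrated",
                                         "original_printed")) {
  if (!is.character(which) || length(which) != 1L ||
      !which %in% c("original", "recalibrated", "original_printed")) {
    stop("unknown definition key ", deparse(substitute(which)),
         "; valid keys: 'original', 'recalibrated', 'original_printed'",
         call. = FALSE)
  }
  cached <- .appsval_env$definitions[[which]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "definitions", paste0(which, ".yaml"),
                      package = "appsval", mustWork = TRUE)
  def <- read_score_definition(path)
  .appsval_env$definitions[[which]] <- def
  def
}

.appsval_env <- new.env(parent = emptyenv())
.appsval_env$definitions <- list()

#' Assign component points for one variable
#'
#' Direction: `age` and `pmax` gain points as the value increases;
#' `pf_ratio` gains points as the value decreases.
#'
#' @param x numeric vector of predictor values (finite, positive).
#' @param variable one of `"age"`, `"pf_ratio"`, `"pmax"`.
#' @param definition an `apps_definition`.
#' @return integer vector of points in 1..3.
#' @export
assign_points <- function(x, variable, definition) {
  stopifnot(inherits(definition, "apps_definition"))
  variable <- match.arg(variable, c("age", "pf_ratio", "pmax"))
  cuts <- definition$cutoffs[[variable]]
  closed <- identical(definition$boundary, "closed")
  if (variable == "pf_ratio") {
    # lower value = worse oxygenation = more points
    if (closed) 1L + (x <= cuts[2]) + (x < cuts[1])
    else        1L + (x <  cuts[2]) + (x <  cuts[1])
  } else {
    if (closed) 1L + (x >= cuts[1]) + (x > cuts[2])
    else        1L + (x >  cuts[1]) + (x >  cuts[2])
  }
}

#' Band table of a definition
#'
#' Expands a definition into one row per band with its half-open/closed
#' interval, printed range label and point value, ordered by points
#' within variable.
#'
#' @param definition an `apps_definition`.
#' @return data.frame with columns `variable`, `points`, `lower`, `upper`,
#'   `range` (printed label).
#' @export
band_table <- function(definition) {
  stopifnot(inherits(definition, "apps_definition"))
  rows <- lapply(c("age", "pf_ratio", "pmax"), function(v) {
    cuts <- definition$cutoffs[[v]]
    if (v == "pf_ratio") {
      lab <- c(paste0(">", cuts[2]), paste0(cuts[1], "-", cuts[2]),
               paste0("<", cuts[1]))
      lower <- c(cuts[2], cuts[1], -Inf)
      upper <- c(Inf, cuts[2], cuts[1])
    } else {
      lab <- c(paste0("<", cuts[1]), paste0(cuts[1], "-", cuts[2]),
               paste0(">", cuts[2]))
      lower <- c(-Inf, cuts[1], cuts[2])
      upper <- c(cuts[1], cuts[2], Inf)
    }
    data.frame(variable = v, points = 1:3, lower = lower, upper = upper,
               range = lab, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.apps_definition <- function(x, ...) {
  cat("<apps_definition> ", x$name, "  (boundary: ", x$boundary, ")\n",
      sep = "")
  bt <- band_table(x)
  for (v in unique(bt$variable)) {
    sub <- bt[bt$variable == v, ]
    cat(sprintf("  %-9s %s\n", v,
                paste(sprintf("%s=%dpt", sub$range, sub$points),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Score a cohort
#'
#' Applies a definition to every patient, returning the cohort with
#' appended component points (`age_pts`, `pf_pts`, `pmax_pts`) and the
#' total score `apps` in 3..9, input order preserved.  Scoring is
#' all-or-nothing: any record with a missing or non-positive required
#' predictor aborts with an error listing the offending record ids.
#'
#' @param cohort data.frame with at least columns `age`, `pf_ratio`,
#'   `pmax` (and usually `id`, `died_in_hospital`).
#' @param definition an `apps_definition`, default the original score.
#' @return The input data.frame with four added integer columns, class
#'   `apps_scored` prepended.
#' @examples
#' co <- data.frame(id = "p1", age = 70, pf_ratio = 90, pmax = 35)
#' score_cohort(co)$apps  # 9
#' @export
score_cohort <- function(cohort, definition = builtin_definition("original")) {
  stopifnot(is.data.frame(cohort), inherits(definition, "apps_definition"))
  need <- c("age", "pf_ratio", "pmax")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- if ("id" %in% names(cohort)) as.character(cohort$id)
         else as.character(seq_len(nrow(cohort)))
  bad <- rep(FALSE, nrow(cohort))
  for (v in need) {
    xv <- cohort[[v]]
    bad <- bad | is.na(xv) | !is.finite(xv) | xv <= 0
  }
  if (any(bad)) {
    stop("cannot score record(s) with missing or non-positive predictors: ",
         paste(utils::head(ids[bad], 10), collapse = ", "),
         if (sum(bad) > 10) sprintf(" (and %d more)", sum(bad) - 10) else "",
         call. = FALSE)
  }
  out <- cohort
  out$age_pts  <- as.integer(assign_points(cohort$age, "age", definition))
  out$pf_pts   <- as.integer(assign_points(cohort$pf_ratio, "pf_ratio",
                                           definition))
  out$pmax_pts <- as.integer(assign_points(cohort$pmax, "pmax", definition))
  out$apps     <- out$age_pts + out$pf_pts + out$pmax_pts
  attr(out, "definition") <- definition
  class(out) <- unique(c("apps_scored", class(out)))
  out
}

#' Read / write a score definition file
#'
#' Definitions are serialized as YAML with one block per variable listing
#' the two interior cutoffs, plus the name and boundary convention.
#'
#' @param path file path.
#' @return `read_score_definition()` returns an `apps_definition`;
#'   `write_score_definition()` returns `path` invisibly.
#' @export
read_score_definition <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$name) || is.null(obj$cutoffs)) {
    stop("definition file must contain 'name' and 'cutoffs'", call. = FALSE)
  }
  score_definition(obj$name,
                   lapply(obj$cutoffs, as.numeric),
                   boundary = if (is.null(obj$boundary)) "closed"
                              else obj$boundary)
}

#' @rdname read_score_definition
#' @param definition an `apps_definition` to serialize.
#' @export
write_score_definition <- function(definition, path) {
  stopifnot(inherits(definition, "apps_definition"))
  yaml::write_yaml(list(name = definition$name,
                        boundary = definition$boundary,
                        cutoffs = definition$cutoffs),
                   path)
  invisible(path)
}
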