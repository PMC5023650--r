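# Shared fixture builders for the test suite.

# cohort whose mortality is logistic-linear in the total score
make_linear_cohort <- function(n, seed, slope = 0.4, target = 0.43,
                               definition = builtin_definition("original")) {
  generate_cohort(cohort_spec(
    n_patients = n, seed = seed,
    mortality = mortality_model(0, slope = slope),
    overall_mortality_target = target,
    definition = definition))
}

# O(n^2) tie-corrected concordance oracle for the AUC
brute_force_auc <- function(scores, outcomes) {
  x <- scores[as.logical(outcomes)]
  y <- scores[!as.logical(outcomes)]
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}

# random patient predictor triples, including exact boundary values
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    id = sprintf("R%05d", seq_len(n)),
    age = sample(c(runif(n, 18, 100), 47, 59, 66), n),
    pf_ratio = sample(c(runif(n, 30, 200), 105, 158), n),
    pmax = sample(c(runif(n, 10, 50), 27, 30, 33), n))
}

# one stratum list for trend tests from counts
strata_from_counts <- function(n, deaths) {
  lapply(seq_along(n), function(i) stratum(as.character(i), n[i], deaths[i]))
}
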