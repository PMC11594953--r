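# shared fixtures: all cohorts are generated in code at test time

small_cohort <- function(n = 60, seed = 101, ...) {
  suppressMessages(generate_cohort(cohort_params(n = n, seed = seed, ...)))
}

# random valid PIH response matrices
random_items <- function(n, seed = 1) {
  set.seed(seed)
  matrix(sample(0:8, n * 12, replace = TRUE), nrow = n,
         dimnames = list(NULL, pih_item_names()))
}
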