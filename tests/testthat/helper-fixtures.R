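# Shared fixtures, all built in code at test time.

# the full task grid
GRID <- seq(30, 180, by = 10)

# a small deterministic design for fast tests
tiny_design <- function(n_pairs = 10, seed = 42) {
  harm_design(n_pairs = n_pairs, seed = seed)
}

# a cohort small enough for MCMC in tests
tiny_cohort <- function(n_subjects = 6, seed = 7, ...) {
  generate_cohort(n_subjects = n_subjects, design = tiny_design(seed = seed),
                  seed = seed, ...)
}

# short sampler profile for tests that only need a functioning fit
test_profile <- function(...) {
  fit_settings(chains = 2, warmup = 300, iter = 300, adapt = 300, ...)
}

# random valid trials drawn uniformly off the grid (for property tests)
random_trials <- function(n, seed) {
  pool <- enumerate_valid_pairs()
  with_seed_test(seed, pool[sample.int(nrow(pool), n, replace = TRUE), ])
}

random_params <- function(seed) {
  with_seed_test(seed, list(alpha = runif(1), phi = rnorm(1, -10, 8),
                            tau = exp(rnorm(1, log(0.15), 0.5))))
}

# local seed helper for test code (mirrors the package-internal one)
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
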