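# shared fixtures, all built in code

# one patient, one eye, exactly linear on the lambda = 1 scale:
# z = 2 + 0.5 t at t = 0, 1, 2  =>  y = z + 1 (since f_1(y) = y - 1)
linear_eye_cohort <- function() {
  ga_cohort(data.frame(patient_id = "P1", eye_id = "OD",
                       time_years = c(0, 1, 2),
                       ga_size_mm2 = 2 + 0.5 * c(0, 1, 2) + 1,
                       age_at_baseline_years = 75))
}

# small realistic bilateral synthetic cohort (defaults unless overridden)
small_cohort <- function(seed, n_patients = 15L, ...) {
  generate_cohort(synthetic_config(n_patients = n_patients, ...),
                  seed = seed)
}

# deterministic cohort: all random-effect SDs zero, fixed visit schedule
noiseless_config <- function(...) {
  args <- list(sigma_Delta = 0, sigma_zeta = 0, sigma_eps = 0,
               spacing_sdlog = 0, age_sd = 0,
               visit_count_probs = c("3" = 1))
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / (abs(y) + 1e-8)), tol)
}
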