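# minimal hand-built fit objects let the onset formulas be checked against
# closed-form arithmetic, independent of any optimizer
constructed_cov_fit <- function(mu_Delta = 4.74, xtilde = 0.42,
                                zeta = 0, gamma = 0, lambda = 0.45) {
  structure(list(lambda = lambda, with_covariables = TRUE,
                 include_stability_intercept = FALSE,
                 coefficients = c(time = xtilde, mu_Delta = mu_Delta),
                 sigma = c(eye = 1, patient = 1, residual = 0.4),
                 ranef = list(patient = c(P1 = zeta), eye = c("P1/OD" = gamma)),
                 xtilde = c("P1/OD" = xtilde),
                 eye_patient = c("P1/OD" = "P1")),
            class = "ga_fit")
}

one_eye_data <- function(age = 75.61) {
  ga_cohort(data.frame(patient_id = "P1", eye_id = "OD",
                       time_years = c(0, 1), ga_size_mm2 = c(4, 5),
                       age_at_baseline_years = age))
}

test_that("the covariable onset formula reproduces the worked value", {
  on <- estimate_onset(constructed_cov_fit(), one_eye_data(),
                       threshold_mm2 = 0.05)
  # f_0.45(0.05)/0.42 - 4.74, 30-digit arithmetic
  expect_equal(on$t0_years, -8.65672696320935, tolerance = 1e-10)
  expect_equal(on$onset_age_years, 75.61 - 8.65672696320935,
               tolerance = 1e-10)
  expect_equal(on$delta_hat_years, 4.74)
  expect_equal(on$onset_age_years,
               on$age_at_baseline_years + on$t0_years)  # exact identity
})

test_that("an eye whose expected baseline size equals the threshold has t0 = 0", {
  thr <- 0.05
  f_thr <- bc_transform(thr, 0.45)
  # choose mu_Delta so that xtilde * mu_Delta = f(threshold) at entry
  fit <- constructed_cov_fit(mu_Delta = f_thr / 0.42)
  on <- estimate_onset(fit, one_eye_data(), threshold_mm2 = thr)
  expect_equal(on$t0_years, 0, tolerance = 1e-12)
  expect_equal(on$onset_age_years, 75.61, tolerance = 1e-12)
})

test_that("t0 increases with the threshold defining onset", {
  d <- one_eye_data()
  fit <- constructed_cov_fit()
  t0s <- vapply(c(0.05, 0.1, 0.5, 1, 2),
                function(th) estimate_onset(fit, d, th)$t0_years, numeric(1))
  expect_true(all(diff(t0s) > 0))
})

test_that("threshold with f_lambda(threshold) = 0 gives t0 = -delta_hat exactly", {
  on <- estimate_onset(constructed_cov_fit(zeta = 1.3, gamma = -0.7),
                       one_eye_data(), threshold_mm2 = 1)  # f(1) = 0
  expect_equal(on$t0_years, -on$delta_hat_years, tolerance = 1e-12)
  expect_equal(on$delta_hat_years, 4.74 + 1.3 - 0.7)
})

test_that("no-covariable onset uses (f - level)/beta and flags beta = 0", {
  g <- small_cohort(seed = 61, n_patients = 15L)
  fit <- fit_no_covariables(g$cohort, 0.45)
  on <- estimate_onset(fit, g$cohort)
  lev <- fit$coefficients["mu_theta"] +
    fit$ranef$patient[on$patient_id] +
    fit$ranef$eye[paste(on$patient_id, on$eye_id, sep = "/")]
  expect_equal(on$t0_years,
               unname((bc_transform(0.05, 0.45) - lev) /
                        fit$coefficients["time"]), tolerance = 1e-10)
  expect_true(all(is.na(on$delta_hat_years)))
  # degenerate enlargement rate
  fit0 <- fit
  fit0$coefficients["time"] <- 0
  on0 <- estimate_onset(fit0, g$cohort)
  expect_true(all(is.na(on0$t0_years)))
  expect_true(all(!is.na(on0$reason)))
})

test_that("onset age shifts one-for-one with baseline age", {
  g <- small_cohort(seed = 62, n_patients = 15L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  on1 <- estimate_onset(fit, g$cohort)
  d <- as.data.frame(g$cohort)
  d$age_at_baseline_years <- d$age_at_baseline_years + 10
  on2 <- estimate_onset(
    fit, ga_cohort(d, covariable_names = covariable_names(g$cohort)))
  expect_equal(on2$t0_years, on1$t0_years)
  expect_equal(on2$onset_age_years, on1$onset_age_years + 10)
  s <- summarize_onset(on1)
  expect_equal(s$value[s$statistic == "mean_onset_age"],
               mean(on1$onset_age_years))
})
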