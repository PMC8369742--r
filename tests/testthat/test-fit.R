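test_that("noiseless linear data are fitted exactly", {
  fit <- fit_no_covariables(linear_eye_cohort(), lambda = 1)
  expect_equal(unname(fit$coefficients["time"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["mu_theta"]), 2, tolerance = 1e-8)
  expect_lt(fit$sigma["residual"], 1e-6)
  expect_equal(fit$n_iterations, 1L)
  expect_lt(max(abs(fit$residuals_z)), 1e-6)
})

test_that("no-covariable fit agrees with lme4 (independent ML oracle)", {
  skip_if_not_installed("lme4")
  g <- small_cohort(seed = 51, n_patients = 40L)
  d <- as.data.frame(g$cohort)
  d$eye_key <- paste(d$patient_id, d$eye_id, sep = "/")
  for (lam in c(0.45, 1)) {
    fit <- fit_no_covariables(g$cohort, lam)
    d$z <- bc_transform(d$ga_size_mm2, lam)
    m <- lme4::lmer(z ~ time_years + (1 | patient_id) + (1 | eye_key),
                    data = d, REML = FALSE)
    expect_equal(fit$loglik_z, as.numeric(logLik(m)), tolerance = 1e-6)
    expect_equal(unname(fit$coefficients[c("mu_theta", "time")]),
                 unname(lme4::fixef(m)), tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(unname(fit$sigma["residual"]),
                 vc$sdcor[vc$grp == "Residual"], tolerance = 1e-3)
    # conditional modes match lme4's BLUPs
    re <- lme4::ranef(m)
    expect_equal(unname(fit$ranef$patient[rownames(re$patient_id)]),
                 re$patient_id[[1]], tolerance = 1e-3)
    expect_equal(unname(fit$ranef$eye[rownames(re$eye_key)]),
                 re$eye_key[[1]], tolerance = 1e-3)
  }
})

test_that("constrained inner fit agrees with lme4 at fixed working covariable", {
  skip_if_not_installed("lme4")
  g <- small_cohort(seed = 52, n_patients = 40L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  d <- as.data.frame(g$cohort)
  d$eye_key <- paste(d$patient_id, d$eye_id, sep = "/")
  d$z <- bc_transform(d$ga_size_mm2, 0.45)
  d$xt <- as.numeric(fit$xtilde[d$eye_key])
  m <- lme4::lmer(
    z ~ time_years + time_years:hyperchol_no + time_years:hypertension_no +
      xt + (0 + xt | patient_id) + (0 + xt | eye_key),
    data = d, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(fit$loglik_z, as.numeric(logLik(m)), tolerance = 1e-4)
  fx <- lme4::fixef(m)
  expect_equal(unname(fit$coefficients["intercept"]),
               unname(fx["(Intercept)"]), tolerance = 1e-2)
  expect_equal(unname(fit$coefficients["time"]),
               unname(fx["time_years"]), tolerance = 1e-3)
  expect_equal(unname(fit$coefficients["mu_Delta"]),
               unname(fx["xt"]), tolerance = 1e-2)
})

test_that("zero covariables nest the covariable model into the simple one", {
  g <- small_cohort(seed = 53, n_patients = 30L)
  d <- as.data.frame(g$cohort)
  d$hyperchol_no <- 0
  d$hypertension_no <- 0
  zero <- ga_cohort(d, covariable_names = c("hyperchol_no", "hypertension_no"))
  fit_c <- suppressWarnings(
    fit_with_covariables(zero, 0.45, include_stability_intercept = FALSE))
  fit_0 <- fit_no_covariables(g$cohort, 0.45)
  expect_equal(fit_c$loglik_z, fit_0$loglik_z, tolerance = 1e-6)
  expect_equal(unname(fit_c$coefficients["time"]),
               unname(fit_0$coefficients["time"]), tolerance = 1e-5)
  # mu_theta = beta * mu_Delta under the reparameterization
  expect_equal(unname(fit_c$coefficients["time"] *
                        fit_c$coefficients["mu_Delta"]),
               unname(fit_0$coefficients["mu_theta"]), tolerance = 1e-4)
})

test_that("the working-covariable iteration reaches a fixed point", {
  g <- small_cohort(seed = 54, n_patients = 40L)
  fit <- fit_with_covariables(g$cohort, 0.45, tol = 1e-6)
  expect_true(fit$converged)
  one_more <- fit_with_covariables(g$cohort, 0.45, tol = 1e-6,
                                   max_iter = 2L, init = fit)
  expect_rel_equal(one_more$coefficients, fit$coefficients, 1e-5)
  # stored xtilde is consistent with the coefficients within tolerance
  idx <- gaprog:::.cohort_index(g$cohort)
  covs <- covariable_names(g$cohort)
  xt_recomputed <- as.numeric(
    fit$coefficients["time"] +
      idx$xmat %*% fit$coefficients[paste0("time:", covs)])
  expect_rel_equal(as.numeric(fit$xtilde), xt_recomputed, 1e-4)
})

test_that("relabeling patients and permuting rows leaves estimates unchanged", {
  g <- small_cohort(seed = 55, n_patients = 25L)
  d <- as.data.frame(g$cohort)
  relab <- d
  map <- stats::setNames(sprintf("Z%02d", rev(seq_along(unique(d$patient_id)))),
                         unique(d$patient_id))
  relab$patient_id <- unname(map[d$patient_id])
  set.seed(1)
  relab <- relab[sample(nrow(relab)), ]
  f1 <- fit_with_covariables(g$cohort, 0.45)
  f2 <- fit_with_covariables(
    ga_cohort(relab, covariable_names = covariable_names(g$cohort)), 0.45)
  expect_equal(unname(f1$coefficients), unname(f2$coefficients),
               tolerance = 1e-6)
  expect_equal(unname(f1$sigma), unname(f2$sigma), tolerance = 1e-6)
  expect_equal(f1$loglik_z, f2$loglik_z, tolerance = 1e-8)
})

test_that("brute-force oracle equals the simple fit when there is no constraint", {
  g <- small_cohort(seed = 56)
  plain <- ga_cohort(as.data.frame(g$cohort))  # drop covariables
  f <- fit_no_covariables(plain, 0.45)
  b <- brute_force_ml(plain, 0.45)
  expect_equal(b$loglik_z, f$loglik_z, tolerance = 1e-5)
  expect_equal(unname(b$coefficients), unname(f$coefficients),
               tolerance = 1e-4)
})

test_that("both likelihood evaluators agree at identical parameters", {
  g <- small_cohort(seed = 57, n_patients = 20L)
  idx <- gaprog:::.cohort_index(g$cohort)
  z <- bc_transform(g$cohort$ga_size_mm2, 0.45)
  X <- cbind(mu_theta = rep(1, nrow(g$cohort)),
             time = g$cohort$time_years)
  w <- rep(1, nrow(g$cohort))
  fast <- gaprog:::cpp_fit_core(z, X, w, idx$patient, idx$eye, c(0, 0))
  slow <- gaprog:::cpp_profile_eval(z, X, w, idx$patient, idx$eye,
                                    fast$psi[1], fast$psi[2])
  expect_equal(fast$loglik, slow$loglik, tolerance = 1e-9)
  expect_equal(as.numeric(fast$beta), as.numeric(slow$beta),
               tolerance = 1e-10)
})

test_that("conditional modes: degenerate prior and single-patient limit", {
  # sigma_delta = sigma_zeta = 0 => all modes 0
  m0 <- gaprog:::cpp_cond_modes(c(1, -1, 2), rep(1, 3), rep(1L, 3),
                                c(1L, 1L, 2L), 0, 0, 1)
  expect_equal(as.numeric(m0$zeta), 0)
  expect_equal(as.numeric(m0$gamma), c(0, 0))
  # huge patient variance, tiny residual: zeta -> mean residual offset
  m1 <- gaprog:::cpp_cond_modes(c(1.2, 1.2, 1.2), rep(1, 3), rep(1L, 3),
                                rep(1L, 3), 0, 1e6, 1e-6)
  expect_equal(as.numeric(m1$zeta), 1.2, tolerance = 1e-4)
  # exported wrapper reproduces the stored modes
  g <- small_cohort(seed = 58, n_patients = 15L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  cm <- conditional_modes(fit, g$cohort)
  expect_equal(cm$patient, fit$ranef$patient, tolerance = 1e-10)
  expect_equal(cm$eye, fit$ranef$eye, tolerance = 1e-10)
})

test_that("residual diagnostics expose the smearing pool unchanged", {
  g <- small_cohort(seed = 59, n_patients = 15L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  rd <- residual_diagnostics(fit, g$cohort)
  expect_equal(rd$residual_z, fit$residuals_z)
  expect_equal(rd$fitted_z + rd$residual_z,
               bc_transform(g$cohort$ga_size_mm2, 0.45), tolerance = 1e-10)
  rd0 <- residual_diagnostics(fit_no_covariables(linear_eye_cohort(), 1),
                              linear_eye_cohort())
  expect_lt(max(abs(rd0$residual_z)), 1e-6)
})

test_that("fit summaries serialize to JSON faithfully", {
  g <- small_cohort(seed = 60, n_patients = 15L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_summary(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$coefficients$mu_Delta,
               unname(fit$coefficients["mu_Delta"]))
  expect_equal(js$variance$patient, unname(fit$sigma["patient"]^2))
  expect_equal(js$n_iterations, fit$n_iterations)
})
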