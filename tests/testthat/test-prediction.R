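test_that("smearing with a degenerate pool equals the naive back-transform", {
  sm <- smearing_mean(c(0.5, 1.5), pool = 0, lambda = 0.45, r = 100, seed = 1)
  expect_equal(sm$y_hat, bc_inverse(c(0.5, 1.5), 0.45))
  expect_equal(sm$n_dropped, c(0L, 0L))
})

test_that("for lambda = 1 the affine inverse commutes with averaging", {
  pool <- c(-0.3, -0.1, 0, 0.2, 0.25)
  sm <- smearing_mean(2, pool, lambda = 1, r = 5e4, seed = 2)
  expect_equal(sm$y_hat, 2 + 1 + mean(pool), tolerance = 5e-3)
})

test_that("smearing converges to exact enumeration over a finite pool", {
  pool <- c(-0.8, -0.2, 0.1, 0.4, 0.9)
  zhat <- 1.2
  exact <- mean(bc_inverse(zhat + pool, 0.45))  # enumeration oracle
  sm <- smearing_mean(zhat, pool, lambda = 0.45, r = 2e5, seed = 3)
  expect_equal(sm$y_hat, exact, tolerance = 3e-3)
})

test_that("for lambda = 0 with Gaussian residuals smearing matches exp(z + s2/2)", {
  set.seed(4)
  pool <- rnorm(20000, 0, 0.5)
  sm <- smearing_mean(1.3, pool, lambda = 0, r = 2e5, seed = 5)
  mc_se <- sd(exp(1.3 + pool)) / sqrt(length(pool))
  expect_equal(sm$y_hat, exp(1.3 + 0.5^2 / 2), tolerance = 3 * mc_se)
})

test_that("identical seeds give identical predictions; draws shape is reported", {
  g <- small_cohort(seed = 71, n_patients = 15L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  p1 <- suppressWarnings(smearing_predict(fit, g$cohort, r = 500, seed = 9))
  p2 <- suppressWarnings(smearing_predict(fit, g$cohort, r = 500, seed = 9))
  expect_identical(p1, p2)
  p3 <- suppressWarnings(smearing_predict(fit, g$cohort, r = 500, seed = 10))
  expect_false(identical(p1$y_hat, p3$y_hat))
  expect_true(all(c("z_hat", "y_hat", "n_dropped", "q025", "q50", "q975")
                  %in% names(p1)))
})

test_that("undefined draws are dropped and counted, never averaged", {
  # z so low that some draws from the pool fall outside the domain
  pool <- c(-1, 0, 1)
  sm <- smearing_mean(-1.8, pool, lambda = 0.45, r = 3000, seed = 11)
  expect_gt(sm$n_dropped, 0)
  expect_true(is.finite(sm$y_hat))
  all_bad <- smearing_mean(-10, pool = c(-1, 0, 1), lambda = 0.45,
                           r = 50, seed = 12)
  expect_true(is.na(all_bad$y_hat))
  expect_equal(all_bad$n_dropped, 50L)
})

test_that("smearing dominates the naive back-transform for lambda < 1 (Jensen)", {
  g <- small_cohort(seed = 72, n_patients = 20L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  sm <- suppressWarnings(smearing_predict(fit, g$cohort, r = 4000, seed = 13))
  nv <- naive_backtransform(fit, g$cohort)
  ok <- is.finite(sm$y_hat) & is.finite(nv$y_hat_naive) & sm$n_dropped == 0
  expect_gt(sum(ok), 0)
  expect_true(all(sm$y_hat[ok] >= nv$y_hat_naive[ok]))
})

test_that("in-sample RMSD is ~0 on noiseless data and seed-stable otherwise", {
  g0 <- generate_cohort(noiseless_config(beta_x = c(hyperchol_no = 0,
                                                    hypertension_no = 0),
                                         n_patients = 10L), seed = 73)
  f0 <- fit_no_covariables(g0$cohort, 0.45)
  expect_lt(rmsd_original_scale(f0, g0$cohort, r = 200, seed = 1), 1e-4)
  g <- small_cohort(seed = 74, n_patients = 25L)
  fit <- fit_with_covariables(g$cohort, 0.45)
  r1 <- suppressWarnings(rmsd_original_scale(fit, g$cohort, r = 1e5, seed = 1))
  r2 <- suppressWarnings(rmsd_original_scale(fit, g$cohort, r = 1e5, seed = 2))
  expect_lt(abs(r1 - r2) / r1, 0.01)
})

test_that("the RMSD lambda sweep returns one row per grid value", {
  g <- small_cohort(seed = 75, n_patients = 15L)
  sw <- suppressWarnings(
    rmsd_lambda_sweep(g$cohort, grid = c(0.3, 0.45, 0.6),
                      with_covariables = TRUE, r = 1000, seed = 3))
  expect_equal(nrow(sw), 3L)
  expect_true(all(sw$ok))
  expect_true(all(is.finite(sw$rmsd)))
})

test_that("next-observation prediction holds out only eyes with enough visits", {
  # noiseless: held-out predictions are exact
  g0 <- generate_cohort(noiseless_config(beta_x = c(hyperchol_no = 0,
                                                    hypertension_no = 0),
                                         visit_count_probs = c("5" = 1),
                                         n_patients = 10L), seed = 76)
  res0 <- predict_next_observation(g0$cohort, lambda = 0.45,
                                   with_covariables = FALSE,
                                   r = 200, seed = 1)
  expect_lt(res0$rmsd, 1e-4)
  # eyes with exactly 3 visits are not evaluated
  g <- generate_cohort(synthetic_config(visit_count_probs = c("3" = 0.5,
                                                              "5" = 0.5),
                                        n_patients = 30L), seed = 77)
  res <- suppressWarnings(
    predict_next_observation(g$cohort, lambda = 0.45, r = 500, seed = 2))
  key <- paste(g$cohort$patient_id, g$cohort$eye_id)
  nv <- table(key)
  held <- paste(res$predictions$patient_id, res$predictions$eye_id)
  expect_true(all(nv[held] >= 4))
  expect_equal(sort(unique(held)), sort(names(nv[nv >= 4])))
  # the training fit never saw the held-out visits
  expect_equal(nrow(res$fit$trace) >= 1, TRUE)
  expect_error(predict_next_observation(
    generate_cohort(synthetic_config(visit_count_probs = c("2" = 1),
                                     n_patients = 5L), seed = 78)$cohort,
    lambda = 0.45), "no eye")
})
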