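#' Per-eye age-of-onset estimation
#'
#' Back-projects each eye's trajectory to the time `t0` (years, typically
#' negative) at which its expected transformed size equalled the transformed
#' clinical onset threshold (default 0.05 mm^2, the lesion area of a 250 um
#' minimum lesion diameter).  Solving the model equation for `t`:
#'
#' * no-covariable model:
#'   `t0 = (f_lambda(threshold) - (mu_theta + zeta_j + alpha_i)) / beta`
#' * covariable model:
#'   `t0 = (f_lambda(threshold) - xtilde_i*(mu_Delta + zeta_j + gamma_i)) / xtilde_i`
#'
#' The estimated age-of-onset is `age_at_baseline + t0`: `t0` carries its
#' sign, so onset before study entry (negative `t0`) gives an onset age below
#' the entry age.  In the covariable model the estimated disease age at entry
#' is `Delta_hat = mu_Delta + zeta_j + gamma_i`; choosing the threshold so
#' that `f_lambda(threshold) = 0` gives `t0 = -Delta_hat` exactly.
#'
#' Eyes whose enlargement rate (`beta`, resp. `xtilde_i`) is ~0 have no
#' defined onset; they are returned with `NA` and a reason.
#'
#' @param fit a `ga_fit`.
#' @param data the [ga_cohort] the model was fitted to.
#' @param threshold_mm2 lesion size defining clinical onset (mm^2).
#' @return data.frame with one row per eye: `patient_id`, `eye_id`,
#'   `age_at_baseline_years`, `t0_years`, `onset_age_years`,
#'   `delta_hat_years` (`NA` for the no-covariable model) and `reason`
#'   (`NA` unless the estimate is undefined).
#' @export
estimate_onset <- function(fit, data, threshold_mm2 = 0.05) {
  stopifnot(inherits(fit, "ga_fit"), inherits(data, "ga_cohort"),
            threshold_mm2 > 0)
  idx <- .cohort_index(data)
  f_thr <- bc_transform(threshold_mm2, fit$lambda)
  eyes <- idx$eyes
  zeta_eye <- fit$ranef$patient[idx$eye_patient]
  gamma_eye <- fit$ranef$eye[eyes]
  if (fit$with_covariables) {
    xt <- as.numeric(fit$xtilde[eyes])
    delta_hat <- fit$coefficients["mu_Delta"] + zeta_eye + gamma_eye
    undef <- abs(xt) < 1e-10
    t0 <- ifelse(undef, NA_real_, f_thr / xt - delta_hat)
    reason <- ifelse(undef, "working covariable xtilde is 0", NA_character_)
  } else {
    beta <- fit$coefficients["time"]
    level <- fit$coefficients["mu_theta"] + zeta_eye + gamma_eye
    undef <- abs(beta) < 1e-10
    t0 <- if (undef) rep(NA_real_, length(eyes)) else (f_thr - level) / beta
    delta_hat <- rep(NA_real_, length(eyes))
    reason <- ifelse(rep(undef, length(eyes)), "enlargement rate beta is 0",
                     NA_character_)
  }
  data.frame(patient_id = idx$eye_patient,
             eye_id = sub("^.*/", "", eyes),
             age_at_baseline_years = idx$age,
             t0_years = as.numeric(t0),
             onset_age_years = idx$age + as.numeric(t0),
             delta_hat_years = as.numeric(delta_hat),
             reason = reason,
             row.names = NULL)
}

#' Summarize estimated onset ages
#'
#' Mean and median onset age with SDs, alongside the observed entry ages —
#' the quantities needed for cohort-level reporting of the back-projection.
#'
#' @param onset output of [estimate_onset()].
#' @return data.frame with one row per summary statistic.
#' @export
summarize_onset <- function(onset) {
  ok <- is.finite(onset$onset_age_years)
  data.frame(
    statistic = c("mean_onset_age", "sd_onset_age", "median_onset_age",
                  "mean_entry_age", "n_eyes", "n_undefined"),
    value = c(mean(onset$onset_age_years[ok]), sd(onset$onset_age_years[ok]),
              stats::median(onset$onset_age_years[ok]),
              mean(onset$age_at_baseline_years), sum(ok), sum(!ok)))
}
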