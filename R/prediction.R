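# Bias-corrected prediction on the original mm^2 scale.
#
# The model is linear only on the transformed scale; because the inverse
# Box-Cox map is convex for lambda < 1, naively back-transforming the linear
# predictor underestimates the expected size (Jensen's inequality).  The
# smearing estimator corrects this by averaging the back-transform over
# residuals resampled from the fitted model's empirical residual pool.

# predicted transformed value (incl. random-effect modes) for (eye, t)
.zhat_fit <- function(fit, eye_keys, t) {
  zeta_eye <- fit$ranef$patient[fit$eye_patient[eye_keys]]
  gamma_eye <- fit$ranef$eye[eye_keys]
  if (anyNA(gamma_eye) || anyNA(zeta_eye)) {
    .stopf("prediction target refers to eye(s) absent from the fit: %s",
           paste(unique(eye_keys[is.na(gamma_eye)]), collapse = ", "))
  }
  if (fit$with_covariables) {
    xt <- as.numeric(fit$xtilde[eye_keys])
    i0 <- if (fit$include_stability_intercept) fit$coefficients["intercept"] else 0
    as.numeric(i0 + xt * (fit$coefficients["mu_Delta"] + gamma_eye + zeta_eye + t))
  } else {
    as.numeric(fit$coefficients["mu_theta"] + fit$coefficients["time"] * t +
                 gamma_eye + zeta_eye)
  }
}

.targets_or_all <- function(data, targets) {
  if (is.null(targets)) {
    targets <- data.frame(patient_id = data$patient_id, eye_id = data$eye_id,
                          time_years = data$time_years)
  }
  stopifnot(all(c("patient_id", "eye_id", "time_years") %in% names(targets)))
  targets
}

#' Smearing mean of a back-transformed prediction
#'
#' Low-level smearing estimator: draws `r` residuals with replacement from
#' `pool` (one shared draw set for all targets), adds them to each `zhat`,
#' back-transforms, and averages the draws whose inverse exists.
#'
#' @param zhat fitted transformed values.
#' @param pool empirical residual pool (transformed scale).
#' @param lambda Box-Cox parameter.
#' @param r number of residual draws.
#' @param seed integer seed (`NULL` = use the current RNG stream).
#' @return data.frame with `y_hat` (mm^2), `n_dropped` (draws with undefined
#'   inverse), and draw quantiles `q025`, `q50`, `q975`.
#' @export
smearing_mean <- function(zhat, pool, lambda, r = 10000L, seed = NULL) {
  stopifnot(r >= 1L, length(pool) >= 1L)
  eps <- with_seed(seed, sample(pool, r, replace = TRUE))
  n <- length(zhat)
  y_hat <- numeric(n)
  n_dropped <- integer(n)
  q <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("q025", "q50", "q975")))
  chunk <- max(1L, floor(2e7 / r))
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(n, s + chunk - 1L)
    draws <- bc_inverse(outer(zhat[i], eps, "+"), lambda)
    dim(draws) <- c(length(i), r)
    n_dropped[i] <- rowSums(is.na(draws))
    y_hat[i] <- rowMeans(draws, na.rm = TRUE)
    q[i, ] <- t(apply(draws, 1, quantile, probs = c(0.025, 0.5, 0.975),
                      na.rm = TRUE, names = FALSE))
  }
  y_hat[n_dropped == r] <- NA_real_
  if (any(n_dropped > 0.01 * r)) {
    .warnf("more than 1%% of smearing draws had an undefined inverse for %d target(s)",
           sum(n_dropped > 0.01 * r))
  }
  data.frame(y_hat = y_hat, n_dropped = n_dropped, q)
}

#' Smearing prediction of expected GA size
#'
#' Estimates the expected lesion size on the original mm^2 scale for each
#' target `(eye, t)` as the average of `f_lambda^{-1}(zhat + eps_u)` over `r`
#' residuals `eps_u` resampled (with replacement, seeded) from the fitted
#' model's residual pool.  Draws whose inverse is undefined are dropped and
#' counted; a target whose draws are all undefined is returned as `NA` with a
#' reason.  Deterministic given `seed`.
#'
#' @param fit a `ga_fit`.
#' @param data the [ga_cohort] the model was fitted to.
#' @param targets data.frame with columns `patient_id`, `eye_id`,
#'   `time_years`; defaults to every observed visit.
#' @param r number of residual draws.
#' @param seed integer seed.
#' @return data.frame: targets plus `z_hat`, `y_hat` (smearing estimate,
#'   mm^2), `n_dropped` and draw quantiles.
#' @export
smearing_predict <- function(fit, data, targets = NULL, r = 10000L,
                             seed = NULL) {
  stopifnot(inherits(fit, "ga_fit"), inherits(data, "ga_cohort"))
  targets <- .targets_or_all(data, targets)
  keys <- .eye_key(targets$patient_id, targets$eye_id)
  zhat <- .zhat_fit(fit, keys, targets$time_years)
  sm <- smearing_mean(zhat, fit$residuals_z, fit$lambda, r = r, seed = seed)
  cbind(targets, z_hat = zhat, sm)
}

#' Naive back-transformation of the linear predictor
#'
#' Returns `f_lambda^{-1}(zhat)` per target — the uncorrected estimate whose
#' gap to [smearing_predict()] quantifies the Jensen bias. Undefined inverses
#' propagate as `NA`.
#'
#' @inheritParams smearing_predict
#' @return data.frame: targets plus `z_hat` and `y_hat_naive`.
#' @export
naive_backtransform <- function(fit, data, targets = NULL) {
  stopifnot(inherits(fit, "ga_fit"), inherits(data, "ga_cohort"))
  targets <- .targets_or_all(data, targets)
  keys <- .eye_key(targets$patient_id, targets$eye_id)
  zhat <- .zhat_fit(fit, keys, targets$time_years)
  cbind(targets, z_hat = zhat, y_hat_naive = bc_inverse(zhat, fit$lambda))
}

#' In-sample RMSD on the original scale
#'
#' Root mean squared difference (mm^2) between the observed sizes and the
#' smearing-predicted expected sizes at each observation's own visit.
#'
#' @inheritParams smearing_predict
#' @return single numeric RMSD in mm^2.
#' @export
rmsd_original_scale <- function(fit, data, r = 10000L, seed = NULL) {
  pred <- smearing_predict(fit, data, r = r, seed = seed)
  ok <- is.finite(pred$y_hat)
  if (!all(ok)) .warnf("%d observation(s) had no defined prediction", sum(!ok))
  sqrt(mean((pred$y_hat[ok] - data$ga_size_mm2[ok])^2))
}

#' RMSD across transformation parameters
#'
#' Refits the model at every lambda on the grid and evaluates the smearing
#' RMSD on the original scale — the prediction-accuracy counterpart of the
#' AIC grid search (their minima need not coincide).
#'
#' @param data a [ga_cohort].
#' @param grid lambda values.
#' @param with_covariables which model to fit at each lambda.
#' @param r,seed passed to [rmsd_original_scale()].
#' @param ... passed to [fit_with_covariables()].
#' @return data.frame with columns `lambda`, `rmsd`, `ok` (plus attribute
#'   `failures` with error messages for failed fits).
#' @export
rmsd_lambda_sweep <- function(data, grid = default_lambda_grid(),
                              with_covariables = FALSE, r = 10000L,
                              seed = NULL, ...) {
  grid <- sort(unique(as.numeric(grid)))
  out <- data.frame(lambda = grid, rmsd = NA_real_, ok = FALSE)
  failures <- character(0)
  init <- NULL
  for (i in seq_along(grid)) {
    res <- tryCatch({
      fit <- if (with_covariables) {
        fit_with_covariables(data, lambda = grid[i], init = init, ...)
      } else {
        fit_no_covariables(data, lambda = grid[i])
      }
      if (with_covariables) init <- fit
      rmsd_original_scale(fit, data, r = r, seed = seed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("lambda = %g: %s", grid[i], conditionMessage(res)))
    } else {
      out$rmsd[i] <- res
      out$ok[i] <- TRUE
    }
  }
  attr(out, "failures") <- failures
  out
}

#' Held-out prediction of each eye's last observation
#'
#' For every eye with at least `min_visits` visits, removes the eye's last
#' visit, fits one shared training model to the reduced cohort, and predicts
#' the held-out sizes by smearing with the training fit's random-effect
#' modes.  (A single shared training fit, rather than one refit per eye, is
#' used for determinism and cost.)
#'
#' @param data a [ga_cohort].
#' @param lambda Box-Cox parameter for the training fit.
#' @param with_covariables which model to fit.
#' @param min_visits minimum visit count for an eye to qualify (default 4,
#'   i.e. more than three visits).
#' @param r,seed smearing parameters.
#' @param ... passed to [fit_with_covariables()].
#' @return list with `predictions` (data.frame `patient_id`, `eye_id`,
#'   `time_years`, `observed_mm2`, `y_hat`), `rmsd` (mm^2 over the held-out
#'   visits) and `fit` (the training `ga_fit`).
#' @export
predict_next_observation <- function(data, lambda, with_covariables = TRUE,
                                     min_visits = 4L, r = 10000L,
                                     seed = NULL, ...) {
  stopifnot(inherits(data, "ga_cohort"), min_visits >= 3L)
  key <- .eye_key(data$patient_id, data$eye_id)
  n_vis <- stats::ave(data$time_years, key, FUN = length)
  is_last <- data$time_years == stats::ave(data$time_years, key, FUN = max)
  held_out <- n_vis >= min_visits & is_last
  if (!any(held_out)) {
    .stopf("no eye has at least %d visits; nothing to predict", min_visits)
  }
  train <- ga_cohort(as.data.frame(data)[!held_out, , drop = FALSE],
                     covariable_names = covariable_names(data))
  fit <- if (with_covariables) {
    fit_with_covariables(train, lambda = lambda, ...)
  } else {
    fit_no_covariables(train, lambda = lambda)
  }
  targets <- data.frame(patient_id = data$patient_id[held_out],
                        eye_id = data$eye_id[held_out],
                        time_years = data$time_years[held_out])
  pred <- smearing_predict(fit, train, targets = targets, r = r, seed = seed)
  predictions <- data.frame(targets,
                            observed_mm2 = data$ga_size_mm2[held_out],
                            y_hat = pred$y_hat)
  ok <- is.finite(predictions$y_hat)
  list(predictions = predictions,
       rmsd = sqrt(mean((predictions$y_hat[ok] -
                           predictions$observed_mm2[ok])^2)),
       fit = fit)
}
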