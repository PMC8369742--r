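# Fitting the disease-age-parameterized mixed-effects model.
#
# Both fitters maximize the exact Gaussian marginal likelihood over
# per-patient blocks: the residual variance and the fixed effects are profiled
# out in closed form (GLS), leaving a 2-D search over the variance ratios
# psi_delta = sigma_delta^2/sigma_eps^2, psi_zeta = sigma_zeta^2/sigma_eps^2,
# done by a compiled Nelder-Mead (see src/loglik.cpp).  This keeps the
# known-loading random-effect structure (xtilde*gamma_i, xtilde*zeta_j) exact.

# crude method-of-moments starting values for the variance ratios
.start_psi <- function(z, X, w, patient, eye) {
  e <- tryCatch(stats::lm.fit(X, z)$residuals, error = function(cnd) z - mean(z))
  eye_mean <- stats::ave(e, eye)
  pat_mean <- stats::ave(e, patient)
  s2w <- stats::var(e - eye_mean)
  if (!is.finite(s2w) || s2w < 1e-12) return(c(1, 1))
  mw2 <- mean(w^2)
  psi_d <- stats::var(eye_mean - pat_mean) / (s2w * mw2)
  psi_z <- stats::var(pat_mean) / (s2w * mw2)
  psi <- c(psi_d, psi_z)
  psi[!is.finite(psi)] <- 1
  pmin(pmax(psi, 1e-3), 1e6)
}

# single maximum-likelihood fit at fixed design X and loading w.
# Returns coefficients (0 for aliased columns), SDs, loglik on the z scale.
.fit_core <- function(z, X, w, patient, eye, lp_start = NULL,
                      reltol = 1e-11, maxit = 800) {
  qx <- qr(X)
  keep <- sort(qx$pivot[seq_len(qx$rank)])
  aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  Xu <- X[, keep, drop = FALSE]
  # a warm start justifies a tighter initial simplex
  step <- if (is.null(lp_start)) 1.0 else 0.35
  if (is.null(lp_start)) lp_start <- log(.start_psi(z, Xu, w, patient, eye))
  res <- cpp_fit_core(z, Xu, w, patient, eye, lp_start,
                      reltol = reltol, maxit = maxit, step = step)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[keep] <- as.numeric(res$beta)
  psi <- as.numeric(res$psi)
  sigma2 <- res$sigma2
  sd_delta <- sqrt(psi[1] * sigma2)
  sd_zeta <- sqrt(psi[2] * sigma2)
  boundary <- c(eye = sd_delta < 1e-6, patient = sd_zeta < 1e-6)
  if (boundary["eye"]) sd_delta <- 0
  if (boundary["patient"]) sd_zeta <- 0
  list(coef = beta, aliased = aliased,
       sigma_eye = sd_delta, sigma_patient = sd_zeta,
       sigma_resid = sqrt(sigma2),
       boundary = boundary, psi = psi, lp = as.numeric(res$lp),
       loglik = res$loglik, n_estimated = length(keep))
}

# design matrix of the working-covariable model (Eq.-(8)-style inner fit):
# z = intercept0 + beta*t + beta_x'x*t + mu_Delta*xtilde + xtilde*gamma +
#     xtilde*zeta + eps
.design_cov <- function(data, idx, xtilde_eye, include_intercept) {
  covs <- colnames(idx$xmat)
  w <- xtilde_eye[idx$eye]
  tt <- data$time_years
  Xx <- idx$xmat[idx$eye, , drop = FALSE] * tt
  X <- cbind(if (include_intercept) rep(1, nrow(data)), tt, Xx, w)
  colnames(X) <- c(if (include_intercept) "intercept", "time",
                   if (length(covs)) paste0("time:", covs), "mu_Delta")
  list(X = X, w = w)
}

# assemble the exported ga_fit object from a converged core fit
.finish_fit <- function(data, idx, lambda, core, with_covariables,
                        xtilde_eye, n_iterations, converged, trace,
                        include_stability_intercept, method) {
  z <- bc_transform(data$ga_size_mm2, lambda)
  if (with_covariables) {
    des <- .design_cov(data, idx, xtilde_eye, include_stability_intercept)
  } else {
    des <- list(X = cbind(mu_theta = rep(1, nrow(data)),
                          time = data$time_years),
                w = rep(1, nrow(data)))
  }
  fixed <- drop(des$X %*% core$coef)
  modes <- cpp_cond_modes(z - fixed, des$w, idx$patient, idx$eye,
                          core$sigma_eye^2, core$sigma_patient^2,
                          core$sigma_resid^2)
  zeta <- stats::setNames(as.numeric(modes$zeta), idx$patients)
  gamma <- stats::setNames(as.numeric(modes$gamma), idx$eyes)
  ranp <- zeta[match(idx$eye_patient, idx$patients)][idx$eye]
  fitted_z <- unname(fixed + des$w * (gamma[idx$eye] + ranp))
  residuals_z <- z - fitted_z
  n_params <- core$n_estimated + 2L + 1L
  loglik_y <- bc_loglik_y(core$loglik, lambda, data$ga_size_mm2)
  fit <- list(
    lambda = lambda,
    with_covariables = with_covariables,
    covariable_names = colnames(idx$xmat),
    include_stability_intercept = include_stability_intercept,
    method = method,
    coefficients = core$coef,
    aliased = core$aliased,
    sigma = c(eye = core$sigma_eye, patient = core$sigma_patient,
              residual = core$sigma_resid),
    boundary = core$boundary,
    psi = core$psi, lp = core$lp,
    ranef = list(patient = zeta, eye = gamma),
    xtilde = if (with_covariables) stats::setNames(xtilde_eye, idx$eyes),
    eye_patient = stats::setNames(idx$eye_patient, idx$eyes),
    fitted_z = fitted_z,
    residuals_z = residuals_z,
    loglik_z = core$loglik,
    loglik_y = loglik_y,
    aic_y = -2 * loglik_y + 2 * n_params,
    n_params = n_params,
    n_iterations = n_iterations,
    converged = converged,
    trace = trace)
  class(fit) <- "ga_fit"
  fit
}

#' Fit the trajectory model without covariables
#'
#' Maximum-likelihood fit of the unconstrained nested random-intercept model
#' on the transformed scale:
#' `z = mu_theta + beta*t + zeta_patient + alpha_eye + eps`,
#' where `mu_theta` is the mean and `alpha_eye` the eye-level deviation of
#' `beta * Delta` (enlargement rate times disease age at entry).  This is a
#' single unconstrained fit (`n_iterations = 1`).
#'
#' @param data a [ga_cohort].
#' @param lambda Box-Cox transformation parameter applied to the response.
#' @return a `ga_fit` object; see [fit_with_covariables()] for the fields.
#' @export
fit_no_covariables <- function(data, lambda) {
  stopifnot(inherits(data, "ga_cohort"))
  validate_ga_cohort(data)
  idx <- .cohort_index(data)
  z <- bc_transform(data$ga_size_mm2, lambda)
  X <- cbind(mu_theta = rep(1, nrow(data)), time = data$time_years)
  w <- rep(1, nrow(data))
  core <- .fit_core(z, X, w, idx$patient, idx$eye)
  .finish_fit(data, idx, lambda, core, with_covariables = FALSE,
              xtilde_eye = NULL, n_iterations = 1L, converged = TRUE,
              trace = NULL, include_stability_intercept = FALSE,
              method = "ml")
}

#' Fit the covariable-constrained trajectory model
#'
#' Fits the disease-age model with covariable-dependent enlargement rates by
#' the iterative working-covariable algorithm: starting from
#' `xtilde_i = 1`, alternately (i) set
#' `xtilde_i <- beta_hat + beta_x_hat' x_i` and (ii) maximize the likelihood of
#' `z = intercept0 + beta*t + beta_x'x_i*t + mu_Delta*xtilde_i +
#' xtilde_i*gamma_i + xtilde_i*zeta_j + eps`
#' with known per-eye loadings `xtilde_i`, until the maximum relative change
#' of `(beta, beta_x, mu_Delta)` falls below `tol`.  A fixed intercept
#' (`intercept0`) is included by default for computational stability; it
#' relaxes the zero-mean constraint on the estimated random effects and is
#' reported (typically near 0).
#'
#' @param data a [ga_cohort] with at least one covariable.
#' @param lambda Box-Cox transformation parameter.
#' @param tol relative convergence tolerance on the coefficients.
#' @param max_iter outer-iteration cap; exceeding it returns a fit flagged
#'   `converged = FALSE` (with a warning) rather than an error.
#' @param include_stability_intercept include the fixed stability intercept?
#' @param init optional `ga_fit` (e.g. a fit at a neighbouring lambda, or the
#'   full-data fit when bootstrapping) used to warm-start `xtilde` and the
#'   variance ratios.
#' @return an object of class `ga_fit`: a list with elements
#'   `coefficients` (named: `intercept`, `time`, `time:<covariable>`,
#'   `mu_Delta`), `sigma` (named SDs `eye`, `patient`, `residual`),
#'   `boundary` (variance components at the zero boundary), `ranef`
#'   (conditional modes: `patient` = zeta, `eye` = gamma), `xtilde` (per-eye
#'   working covariable used in the final inner fit), `fitted_z` /
#'   `residuals_z` (row-aligned with the sorted cohort; fitted values include
#'   the random-effect modes), `loglik_z`, `loglik_y`, `aic_y`, `n_params`,
#'   `n_iterations`, `converged` and `trace` (per-iteration coefficients).
#' @export
fit_with_covariables <- function(data, lambda, tol = 1e-6, max_iter = 50L,
                                 include_stability_intercept = TRUE,
                                 init = NULL) {
  stopifnot(inherits(data, "ga_cohort"), tol > 0, max_iter >= 1L)
  validate_ga_cohort(data)
  covs <- covariable_names(data)
  if (!length(covs)) {
    .stopf("cohort has no covariables; use fit_no_covariables()")
  }
  idx <- .cohort_index(data)
  z <- bc_transform(data$ga_size_mm2, lambda)
  n_eyes <- length(idx$eyes)

  xtilde <- rep(1, n_eyes)
  lp_start <- NULL
  if (inherits(init, "ga_fit") && init$with_covariables) {
    b0 <- init$coefficients["time"]
    bx0 <- init$coefficients[paste0("time:", covs)]
    xtilde <- as.numeric(b0 + idx$xmat %*% bx0)
    lp_start <- init$lp
  }

  cf_names <- c(if (include_stability_intercept) "intercept", "time",
                paste0("time:", covs), "mu_Delta")
  track <- c("time", paste0("time:", covs), "mu_Delta")
  prev <- NULL
  trace <- matrix(NA_real_, nrow = 0, ncol = length(cf_names),
                  dimnames = list(NULL, cf_names))
  converged <- FALSE
  core <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    des <- .design_cov(data, idx, xtilde, include_stability_intercept)
    core <- .fit_core(z, des$X, des$w, idx$patient, idx$eye,
                      lp_start = lp_start)
    lp_start <- core$lp
    cf <- core$coef
    trace <- rbind(trace, cf[cf_names])
    if (!is.null(prev)) {
      rel <- max(abs(cf[track] - prev[track]) / (abs(prev[track]) + 1e-8))
      if (rel < tol) { converged <- TRUE; break }
    }
    prev <- cf
    xtilde_new <- as.numeric(cf["time"] +
                               idx$xmat %*% cf[paste0("time:", covs)])
    if (any(abs(xtilde_new) < 1e-8)) {
      .warnf("working covariable is ~0 for %d eye(s): random-effect loading vanishes there",
             sum(abs(xtilde_new) < 1e-8))
    }
    xtilde <- xtilde_new
  }
  if (!converged) {
    .warnf("working-covariable iteration did not converge in %d iterations (tol %g)",
           max_iter, tol)
  }
  .finish_fit(data, idx, lambda, core, with_covariables = TRUE,
              xtilde_eye = xtilde, n_iterations = iter,
              converged = converged, trace = trace,
              include_stability_intercept = include_stability_intercept,
              method = "iterative")
}

#' Brute-force constrained maximum likelihood (testing oracle)
#'
#' Directly maximizes, with a general-purpose optimizer, the exact marginal
#' Gaussian log-likelihood of the constrained model in which the working
#' covariable `xtilde_i = beta + beta_x'x_i` is recomputed from the current
#' coefficients *inside* the objective (the constraint is exact, not
#' iterated).  Intended as an independent cross-check of
#' [fit_with_covariables()] on small cohorts (guideline: at most ~40 eyes);
#' it is far slower than the iterative algorithm.
#'
#' @inheritParams fit_with_covariables
#' @param start optional named start vector with elements `intercept` (if the
#'   stability intercept is included), `time`, `time:<covariable>`,
#'   `mu_Delta`, `log_sd_eye`, `log_sd_patient`, `log_sd_resid`.  Defaults to
#'   a single inner fit at `xtilde = 1`.
#' @return a `ga_fit` with `method = "brute_force"`.
#' @export
brute_force_ml <- function(data, lambda, include_stability_intercept = TRUE,
                           start = NULL) {
  stopifnot(inherits(data, "ga_cohort"))
  validate_ga_cohort(data)
  covs <- covariable_names(data)
  idx <- .cohort_index(data)
  z <- bc_transform(data$ga_size_mm2, lambda)
  tt <- data$time_years
  n <- nrow(data)
  with_cov <- length(covs) > 0L

  if (with_cov) {
    cf_names <- c(if (include_stability_intercept) "intercept", "time",
                  paste0("time:", covs), "mu_Delta")
  } else {
    cf_names <- c("mu_theta", "time")
  }
  par_names <- c(cf_names, "log_sd_eye", "log_sd_patient", "log_sd_resid")

  if (is.null(start)) {
    if (with_cov) {
      des <- .design_cov(data, idx, rep(1, length(idx$eyes)),
                         include_stability_intercept)
      c0 <- .fit_core(z, des$X, des$w, idx$patient, idx$eye)
    } else {
      X0 <- cbind(mu_theta = rep(1, n), time = tt)
      c0 <- .fit_core(z, X0, rep(1, n), idx$patient, idx$eye)
    }
    start <- c(c0$coef[cf_names],
               log_sd_eye = log(max(c0$sigma_eye, 1e-2)),
               log_sd_patient = log(max(c0$sigma_patient, 1e-2)),
               log_sd_resid = log(max(c0$sigma_resid, 1e-3)))
  }
  start <- start[par_names]
  if (anyNA(start)) .stopf("start vector must name: %s",
                           paste(par_names, collapse = ", "))

  negll <- function(par) {
    cf <- par[seq_along(cf_names)]
    names(cf) <- cf_names
    sds <- exp(pmin(pmax(par[length(cf_names) + 1:3], -20), 20))
    if (with_cov) {
      xt_eye <- as.numeric(cf["time"] + idx$xmat %*% cf[paste0("time:", covs)])
      w <- xt_eye[idx$eye]
      mu <- (if (include_stability_intercept) cf["intercept"] else 0) +
        cf["time"] * tt +
        drop((idx$xmat[idx$eye, , drop = FALSE] * tt) %*%
               cf[paste0("time:", covs)]) +
        cf["mu_Delta"] * w
    } else {
      w <- rep(1, n)
      mu <- cf["mu_theta"] + cf["time"] * tt
    }
    ll <- cpp_gauss_loglik(z - mu, w, idx$patient, idx$eye,
                           sds[1]^2, sds[2]^2, sds[3]^2)
    if (!is.finite(ll)) 1e100 else -ll
  }

  opt <- optim(start, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt <- optim(opt$par, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  if (!is.finite(opt$value) || opt$value >= 1e99) {
    .stopf("brute-force optimizer failed (final value %g)", opt$value)
  }
  par <- opt$par
  cf <- stats::setNames(par[seq_along(cf_names)], cf_names)
  sds <- exp(par[length(cf_names) + 1:3])
  boundary <- c(eye = sds[1] < 1e-6, patient = sds[2] < 1e-6)
  core <- list(coef = cf, aliased = character(0),
               sigma_eye = if (boundary[1]) 0 else sds[1],
               sigma_patient = if (boundary[2]) 0 else sds[2],
               sigma_resid = sds[3],
               boundary = boundary,
               psi = (sds[1:2] / sds[3])^2,
               lp = 2 * log(pmax(sds[1:2], 1e-12) / sds[3]),
               loglik = -opt$value,
               n_estimated = length(cf_names))
  xt_eye <- if (with_cov) {
    as.numeric(cf["time"] + idx$xmat %*% cf[paste0("time:", covs)])
  }
  .finish_fit(data, idx, lambda, core, with_covariables = with_cov,
              xtilde_eye = xt_eye, n_iterations = 1L, converged = TRUE,
              trace = NULL,
              include_stability_intercept = with_cov && include_stability_intercept,
              method = "brute_force")
}

#' Conditional modes of the random effects
#'
#' Recomputes the empirical-Bayes (posterior) modes of the patient effects
#' `zeta_j` and eye effects `gamma_i` (or `alpha_i` in the no-covariable
#' model) given the data and the fit's plugged-in ML parameters, via a
#' closed-form generalized-least-squares solve per patient block.  Equal to
#' `fit$ranef`; exposed so modes can be recomputed for any parameter set.
#'
#' @param fit a `ga_fit`.
#' @param data the [ga_cohort] the model was fitted to.
#' @return list with named numeric vectors `patient` and `eye`.
#' @export
conditional_modes <- function(fit, data) {
  stopifnot(inherits(fit, "ga_fit"), inherits(data, "ga_cohort"))
  idx <- .cohort_index(data)
  z <- bc_transform(data$ga_size_mm2, fit$lambda)
  if (fit$with_covariables) {
    xt <- fit$xtilde[idx$eyes]
    des <- .design_cov(data, idx, as.numeric(xt),
                       fit$include_stability_intercept)
  } else {
    des <- list(X = cbind(mu_theta = rep(1, nrow(data)),
                          time = data$time_years),
                w = rep(1, nrow(data)))
  }
  fixed <- drop(des$X %*% fit$coefficients[colnames(des$X)])
  modes <- cpp_cond_modes(z - fixed, des$w, idx$patient, idx$eye,
                          fit$sigma["eye"]^2, fit$sigma["patient"]^2,
                          fit$sigma["residual"]^2)
  list(patient = stats::setNames(as.numeric(modes$zeta), idx$patients),
       eye = stats::setNames(as.numeric(modes$gamma), idx$eyes))
}

#' Residual diagnostics table
#'
#' Per-observation fitted values (including the random-effect modes) and
#' residuals on the transformed scale — the exact inputs for residual-vs-fitted
#' and QQ diagnostics, and the single source of the smearing residual pool.
#'
#' @param fit a `ga_fit`.
#' @param data the [ga_cohort] the model was fitted to.
#' @return data.frame with columns `patient_id`, `eye_id`, `time_years`,
#'   `fitted_z`, `residual_z`.
#' @export
residual_diagnostics <- function(fit, data) {
  stopifnot(inherits(fit, "ga_fit"), inherits(data, "ga_cohort"))
  data.frame(patient_id = data$patient_id, eye_id = data$eye_id,
             time_years = data$time_years,
             fitted_z = fit$fitted_z, residual_z = fit$residuals_z)
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("GA trajectory model (%s, lambda = %g)\n",
              if (x$with_covariables) "with covariables" else "no covariables",
              x$lambda))
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  if (length(x$aliased)) {
    cat("  aliased (not estimated):", paste(x$aliased, collapse = ", "), "\n")
  }
  cat("Random-effect SDs:\n")
  print(round(x$sigma, 4))
  if (any(x$boundary)) {
    cat("  at zero boundary:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  cat(sprintf("logLik(z) = %.3f, logLik(y) = %.3f, AIC(y) = %.2f [%d params]\n",
              x$loglik_z, x$loglik_y, x$aic_y, x$n_params))
  cat(sprintf("iterations = %d, converged = %s\n",
              x$n_iterations, x$converged))
  invisible(x)
}

#' Export a machine-readable fit summary
#'
#' Writes coefficients, variance components (as SD and variance), likelihoods
#' and convergence information as JSON.
#'
#' @param fit a `ga_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "ga_fit"))
  out <- list(
    lambda = fit$lambda,
    with_covariables = fit$with_covariables,
    method = fit$method,
    coefficients = as.list(fit$coefficients),
    sigma = as.list(fit$sigma),
    variance = as.list(fit$sigma^2),
    boundary = as.list(fit$boundary),
    loglik_z = fit$loglik_z, loglik_y = fit$loglik_y,
    aic_y = fit$aic_y, n_params = fit$n_params,
    n_iterations = fit$n_iterations, converged = fit$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
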