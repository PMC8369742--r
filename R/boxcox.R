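#' Box-Cox transformation of lesion size
#'
#' `f_lambda(y) = (y^lambda - 1) / lambda` for `lambda != 0` and `log(y)` for
#' `lambda = 0`.  `lambda = 1` leaves growth linear, `lambda = 0.5` corresponds
#' to a square-root (linear-radius) model and `lambda = 0` to exponential
#' enlargement.  Computed via `expm1()` so the family is numerically continuous
#' in `lambda` at 0.
#'
#' @param y positive lesion sizes (mm^2); vectorized.
#' @param lambda single transformation parameter.
#' @return transformed sizes (unitless), same length as `y`.
#' @seealso [bc_inverse()], [grid_search()]
#' @export
#' @examples
#' bc_transform(3, 1)        # 2
#' bc_transform(exp(1), 0)   # 1
bc_transform <- function(y, lambda) {
  stopifnot(is.numeric(y), length(lambda) == 1L, is.finite(lambda))
  if (any(!is.finite(y)) || any(y <= 0)) {
    .stopf("Box-Cox transform requires strictly positive finite sizes (got min %g)",
           suppressWarnings(min(y)))
  }
  if (lambda == 0) log(y) else expm1(lambda * log(y)) / lambda
}

#' Inverse Box-Cox transformation
#'
#' Maps a transformed value back to the mm^2 scale:
#' `(lambda * z + 1)^(1/lambda)` for `lambda != 0`, `exp(z)` for `lambda = 0`.
#' Where the inverse does not exist (`lambda * z + 1 <= 0`) the result is
#' `NA`, a value rather than an error: callers such as the smearing predictor
#' count and drop undefined draws.
#'
#' @param z transformed sizes; vectorized.
#' @param lambda single transformation parameter.
#' @return sizes in mm^2, `NA` where the inverse is undefined.
#' @export
bc_inverse <- function(z, lambda) {
  stopifnot(is.numeric(z), length(lambda) == 1L, is.finite(lambda))
  if (lambda == 0) return(exp(z))
  u <- lambda * z
  out <- rep(NA_real_, length(z))
  ok <- is.finite(u) & u > -1
  out[ok] <- exp(log1p(u[ok]) / lambda)
  out
}

#' Jacobian-corrected log-likelihood on the original scale
#'
#' Likelihoods of models fitted to differently transformed responses are only
#' comparable after mapping back to the density of the observed sizes.  By the
#' density transformation theorem the correction is the log-Jacobian of the
#' Box-Cox map, `(lambda - 1) * sum(log(y))`, added to the transformed-scale
#' log-likelihood.
#'
#' @param loglik_transformed maximized log-likelihood on the transformed scale.
#' @param lambda transformation parameter used for the fit.
#' @param y all observed sizes (mm^2) entering the fit.
#' @return log-likelihood on the original mm^2 scale.
#' @export
bc_loglik_y <- function(loglik_transformed, lambda, y) {
  stopifnot(length(loglik_transformed) == 1L, length(lambda) == 1L)
  if (any(!is.finite(y)) || any(y <= 0)) {
    .stopf("Jacobian correction requires strictly positive sizes")
  }
  loglik_transformed + (lambda - 1) * sum(log(y))
}

#' Default transformation-parameter grid
#'
#' 0.05 to 1.50 in steps of 0.05, plus the log model `lambda = 0`; spans the
#' linear (1), square-root (0.5) and exponential (0) growth models used in the
#' GA literature.
#'
#' @return increasing numeric vector of lambda values.
#' @export
default_lambda_grid <- function() c(0, seq(0.05, 1.5, by = 0.05))

#' Grid search for the Box-Cox transformation parameter
#'
#' Fits the trajectory model at every lambda on the grid (after transforming
#' the response) and compares Jacobian-corrected AIC values on the original
#' mm^2 scale.  The number of estimated parameters is constant across the grid
#' for a fixed model structure, so the argmin of AIC equals the argmin of
#' `-2 * loglik_y`; lambda itself is held fixed within each fit and is not
#' counted.  Ties are broken toward the smaller lambda.
#'
#' @param data a [ga_cohort] object.
#' @param grid increasing vector of lambda values (default
#'   [default_lambda_grid()]).
#' @param with_covariables fit the covariable-constrained model (`TRUE`) or
#'   the plain nested random-intercept model (`FALSE`, default)?
#' @param ... passed to [fit_with_covariables()] when `with_covariables`.
#' @return object of class `ga_grid_search`: list with elements `table`
#'   (data.frame `lambda`, `loglik_y`, `aic_y`, `ok`), `lambda_opt`, `fits`
#'   (list of [ga_fit][fit_no_covariables] objects, `NULL` where fitting
#'   failed) and `failures` (character messages per failed lambda).
#' @export
grid_search <- function(data, grid = default_lambda_grid(),
                        with_covariables = FALSE, ...) {
  stopifnot(inherits(data, "ga_cohort"), length(grid) >= 1L)
  grid <- sort(unique(as.numeric(grid)))
  fits <- vector("list", length(grid))
  failures <- character(0)
  tab <- data.frame(lambda = grid, loglik_y = NA_real_, aic_y = NA_real_,
                    ok = FALSE)
  init <- NULL
  for (i in seq_along(grid)) {
    fit <- tryCatch(
      if (with_covariables) {
        fit_with_covariables(data, lambda = grid[i], init = init, ...)
      } else {
        fit_no_covariables(data, lambda = grid[i])
      },
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures,
                    sprintf("lambda = %g: %s", grid[i], conditionMessage(fit)))
      next
    }
    fits[[i]] <- fit
    tab$loglik_y[i] <- fit$loglik_y
    tab$aic_y[i] <- fit$aic_y
    tab$ok[i] <- TRUE
    # warm-start the next grid point from this solution
    if (with_covariables) init <- fit
  }
  if (!any(tab$ok)) {
    .stopf("model fitting failed at every lambda on the grid:\n%s",
           paste(failures, collapse = "\n"))
  }
  lambda_opt <- tab$lambda[which.min(tab$aic_y)]  # first minimum = smallest lambda
  structure(list(table = tab, lambda_opt = lambda_opt, fits = fits,
                 failures = failures, with_covariables = with_covariables),
            class = "ga_grid_search")
}

#' @export
print.ga_grid_search <- function(x, ...) {
  cat(sprintf("Box-Cox grid search (%s covariables), %d lambda values\n",
              if (x$with_covariables) "with" else "without",
              nrow(x$table)))
  cat(sprintf("  lambda_opt = %g (AIC = %.2f on the mm^2 scale)\n",
              x$lambda_opt, min(x$table$aic_y, na.rm = TRUE)))
  if (length(x$failures)) {
    cat("  failed fits:\n")
    for (f in x$failures) cat("   ", f, "\n")
  }
  invisible(x)
}
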