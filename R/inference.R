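# Patient-cluster bootstrap for the fixed-effect coefficients.
#
# The patient is the outermost exchangeable unit, so whole patients (with all
# their eyes and visits) are resampled with replacement; duplicated patients
# receive fresh identifiers so the nested random-effect structure treats them
# as distinct clusters.  lambda is held fixed across replicates: re-selecting
# it per replicate would change the estimand.

# one cluster-bootstrap resample of a cohort (uses the current RNG stream);
# `pieces` allows precomputing the per-patient split across replicates
.resample_patients <- function(data, pieces = NULL) {
  if (is.null(pieces)) pieces <- split(as.data.frame(data), data$patient_id)
  picked <- sample(length(pieces), length(pieces), replace = TRUE)
  out <- vector("list", length(picked))
  for (i in seq_along(picked)) {
    df <- pieces[[picked[i]]]
    df$patient_id <- sprintf("bs%03d_%s", i, df$patient_id)
    out[[i]] <- df
  }
  ga_cohort(do.call(rbind, out), covariable_names = covariable_names(data))
}

#' Patient-cluster bootstrap confidence intervals
#'
#' Percentile bootstrap CIs for the fixed-effect coefficients of the
#' trajectory model at fixed `lambda`.  Each replicate resamples patients
#' with replacement (keeping every eye and visit of a sampled patient
#' together) and refits the model, warm-started from the full-data fit.
#' Replicates whose fit fails are counted and excluded; more than 10%
#' failures is an error.  Deterministic given `seed`.
#'
#' @param data a [ga_cohort].
#' @param lambda fixed Box-Cox parameter (typically the AIC-optimal value).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param level confidence level.
#' @param with_covariables which model to fit.
#' @param ... passed to [fit_with_covariables()].
#' @return object of class `ga_bootstrap`: list with `table` (data.frame
#'   `coefficient`, `estimate`, `ci_lower`, `ci_upper`), `replicates`
#'   (B_ok x p matrix of per-replicate coefficients), `B`, `n_failed`,
#'   `level`, `lambda` and `fit` (the full-data fit).
#' @export
bootstrap_ci <- function(data, lambda, B = 1000L, seed = NULL, level = 0.95,
                         with_covariables = TRUE, ...) {
  stopifnot(inherits(data, "ga_cohort"), B >= 1L, level > 0, level < 1)
  fit_fun <- function(d, init = NULL) {
    if (with_covariables) {
      fit_with_covariables(d, lambda = lambda, init = init, ...)
    } else {
      fit_no_covariables(d, lambda = lambda)
    }
  }
  full <- fit_fun(data)
  cf_names <- names(full$coefficients)
  pieces <- split(as.data.frame(data), data$patient_id)
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = B, ncol = length(cf_names),
                  dimnames = list(NULL, cf_names))
    for (b in seq_len(B)) {
      res <- tryCatch({
        boot <- .resample_patients(data, pieces = pieces)
        suppressWarnings(fit_fun(boot, init = full))$coefficients
      }, error = function(e) NULL)
      if (!is.null(res)) out[b, ] <- res[cf_names]
    }
    out
  })
  failed <- rowSums(is.na(reps)) > 0
  n_failed <- sum(failed)
  if (n_failed > 0.1 * B) {
    .stopf("%d of %d bootstrap replicates failed to fit; model too fragile for these data",
           n_failed, B)
  }
  reps <- reps[!failed, , drop = FALSE]
  a <- (1 - level) / 2
  ci <- apply(reps, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- list(table = data.frame(coefficient = cf_names,
                                 estimate = as.numeric(full$coefficients),
                                 ci_lower = ci[1, ], ci_upper = ci[2, ],
                                 row.names = NULL),
              replicates = reps, B = B, n_failed = n_failed,
              level = level, lambda = lambda, fit = full)
  class(out) <- "ga_bootstrap"
  out
}

#' @export
print.ga_bootstrap <- function(x, ...) {
  cat(sprintf("Patient-cluster bootstrap (B = %d, %d failed, %.0f%% percentile CIs, lambda = %g)\n",
              x$B, x$n_failed, 100 * x$level, x$lambda))
  tab <- x$table
  tab$estimate <- round(tab$estimate, 4)
  tab$ci_lower <- round(tab$ci_lower, 4)
  tab$ci_upper <- round(tab$ci_upper, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
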