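#' Longitudinal GA cohort container
#'
#' A `ga_cohort` is a validated data.frame with one row per eye-visit, sorted
#' by patient, eye and time, carrying the columns
#' `patient_id` (character), `eye_id` (character, unique within patient),
#' `time_years` (years since that eye's baseline visit, 0 at baseline),
#' `ga_size_mm2` (strictly positive lesion size) and
#' `age_at_baseline_years` (patient age at the eye's baseline visit; stored
#' per eye because the two eyes of a patient may enter at different visits),
#' plus one numeric column per covariable.  Covariables are time-constant at
#' the eye level; binary risk factors are coded 0/1 by the caller (the
#' conventional coding puts the *absence* of the risk factor at 1, matching
#' the reference levels of the reported model).
#'
#' @param records data.frame with the mandatory columns above plus any
#'   covariable columns.
#' @param covariable_names character vector naming the covariable columns
#'   (possibly empty).
#' @return a `ga_cohort` object (data.frame subclass with attribute
#'   `covariable_names`).
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
ga_cohort <- function(records, covariable_names = character(0)) {
  mandatory <- c("patient_id", "eye_id", "time_years", "ga_size_mm2",
                 "age_at_baseline_years")
  missing_cols <- setdiff(c(mandatory, covariable_names), names(records))
  if (length(missing_cols)) {
    .stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, c(mandatory, covariable_names),
                                    drop = FALSE]
  records$patient_id <- as.character(records$patient_id)
  records$eye_id <- as.character(records$eye_id)
  for (cl in c("time_years", "ga_size_mm2", "age_at_baseline_years",
               covariable_names)) {
    records[[cl]] <- as.numeric(records[[cl]])
  }
  ord <- order(records$patient_id, records$eye_id, records$time_years)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  out <- structure(records,
                   covariable_names = as.character(covariable_names),
                   class = c("ga_cohort", "data.frame"))
  validate_ga_cohort(out)
  out
}

#' Validate a GA cohort
#'
#' Checks every model precondition and fails loudly (naming offending rows or
#' eyes) rather than silently dropping data: strictly positive sizes, a
#' baseline visit (`time_years = 0`) with distinct visit times per eye, at
#' least two visits per eye (the study inclusion filter, made explicit), no
#' missing values, and eye-constant covariables.
#'
#' @param x a `ga_cohort`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_ga_cohort <- function(x) {
  covs <- covariable_names(x)
  num_cols <- c("time_years", "ga_size_mm2", "age_at_baseline_years", covs)
  for (cl in num_cols) {
    bad <- which(!is.finite(x[[cl]]))
    if (length(bad)) {
      .stopf("column %s has missing/non-finite values in row(s): %s",
             cl, paste(head(bad, 10L), collapse = ", "))
    }
  }
  bad <- which(x$ga_size_mm2 <= 0)
  if (length(bad)) {
    .stopf("ga_size_mm2 must be > 0 (Box-Cox transform); offending row(s): %s",
           paste(head(bad, 10L), collapse = ", "))
  }
  bad <- which(x$time_years < 0)
  if (length(bad)) {
    .stopf("time_years must be >= 0; offending row(s): %s",
           paste(head(bad, 10L), collapse = ", "))
  }
  key <- .eye_key(x$patient_id, x$eye_id)
  tt <- split(x$time_years, key)
  no_baseline <- names(tt)[!vapply(tt, function(v) any(v == 0), logical(1))]
  if (length(no_baseline)) {
    .stopf("eye(s) without a baseline visit (time_years = 0): %s",
           paste(head(no_baseline, 10L), collapse = ", "))
  }
  dup <- names(tt)[vapply(tt, anyDuplicated, integer(1)) > 0L]
  if (length(dup)) {
    .stopf("duplicate visit times within eye(s): %s",
           paste(head(dup, 10L), collapse = ", "))
  }
  few <- names(tt)[lengths(tt) < 2L]
  if (length(few)) {
    .stopf("eye(s) with fewer than 2 visits (study inclusion filter): %s",
           paste(head(few, 10L), collapse = ", "))
  }
  for (cl in c("age_at_baseline_years", covs)) {
    v <- split(x[[cl]], key)
    varies <- names(v)[vapply(v, function(u) max(u) - min(u) > 0, logical(1))]
    if (length(varies)) {
      .stopf("column %s must be constant within an eye; varying eye(s): %s",
             cl, paste(head(varies, 10L), collapse = ", "))
    }
  }
  invisible(x)
}

#' @rdname ga_cohort
#' @param x a `ga_cohort`.
#' @export
covariable_names <- function(x) attr(x, "covariable_names") %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GA cohort from a CSV file
#'
#' Expects a comma-separated table with a header row containing
#' `patient_id`, `eye_id`, `time_years`, `ga_size_mm2`,
#' `age_at_baseline_years` plus one column per requested covariable.
#' Covariable coding is taken as-is (encode binaries as 0/1 upstream).
#'
#' @param path file path.
#' @param covariable_names covariable columns to retain.
#' @return a validated [ga_cohort].
#' @export
read_cohort <- function(path, covariable_names = character(0)) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character",
                                eye_id = "character"))
  ga_cohort(df, covariable_names = covariable_names)
}

#' Write a GA cohort to a CSV file
#'
#' Emits the same format [read_cohort()] accepts; `read_cohort(write_cohort(x))`
#' reproduces `x` up to row order (numeric values are written with 15
#' significant digits).
#'
#' @param data a [ga_cohort].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  stopifnot(inherits(data, "ga_cohort"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ga_cohort <- function(x, ...) {
  key <- .eye_key(x$patient_id, x$eye_id)
  covs <- covariable_names(x)
  cat(sprintf("GA cohort: %d patients, %d eyes, %d visits\n",
              length(unique(x$patient_id)), length(unique(key)), nrow(x)))
  base <- x$ga_size_mm2[x$time_years == 0]
  cat(sprintf("  baseline size: mean %.2f mm^2 (range %.2f - %.2f)\n",
              mean(base), min(base), max(base)))
  cat(sprintf("  covariables: %s\n",
              if (length(covs)) paste(covs, collapse = ", ") else "(none)"))
  invisible(x)
}

# internal: per-eye design summary used by the fitters
# returns list with row-level integer codes (patients/eyes contiguous after
# the ga_cohort sort), eye-level covariable matrix, ages, keys
.cohort_index <- function(data) {
  key <- .eye_key(data$patient_id, data$eye_id)
  pat_code <- match(data$patient_id, unique(data$patient_id))
  eye_code <- match(key, unique(key))
  first <- !duplicated(key)
  covs <- covariable_names(data)
  xmat <- as.matrix(data[first, covs, drop = FALSE])
  rownames(xmat) <- key[first]
  list(patient = as.integer(pat_code), eye = as.integer(eye_code),
       eye_key = key, patients = unique(data$patient_id),
       eyes = unique(key), xmat = xmat,
       eye_patient = data$patient_id[first],
       age = data$age_at_baseline_years[first])
}
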