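#' Fill in derived subject-level variables
#'
#' Adds the variables computed from raw measurements: better-eye and
#' worse-eye visual acuity (logMAR, where larger is worse, so the better
#' eye takes the minimum), body-mass index from height and weight, and
#' better/worse monocular mean deviation (dB, where larger is better, so
#' the better eye takes the maximum) when the monocular MDs are present.
#'
#' @param cohort data frame with one row per subject; must contain
#'   `va_right` and `va_left` (logMAR), optionally `height` (cm) and
#'   `weight` (kg), optionally `md_right` and `md_left` (dB).
#' @return The cohort with `va_better`, `va_worse`, `bmi` and (when MDs
#'   are available) `md_better`, `md_worse` filled in. Subjects with a
#'   missing VA get `incomplete = TRUE` instead of derived VA values.
#' @export
derive_variables <- function(cohort) {
  stopifnot(is.data.frame(cohort), all(c("va_right", "va_left") %in% names(cohort)))
  cohort$incomplete <- is.na(cohort$va_right) | is.na(cohort$va_left)
  cohort$va_better <- ifelse(cohort$incomplete, NA_real_,
    pmin(cohort$va_right, cohort$va_left)
  )
  cohort$va_worse <- ifelse(cohort$incomplete, NA_real_,
    pmax(cohort$va_right, cohort$va_left)
  )
  if (all(c("height", "weight") %in% names(cohort))) {
    cohort$bmi <- cohort$weight / (cohort$height / 100)^2
  }
  if (all(c("md_right", "md_left") %in% names(cohort))) {
    cohort$md_better <- pmax(cohort$md_right, cohort$md_left)
    cohort$md_worse <- pmin(cohort$md_right, cohort$md_left)
  }
  cohort
}

#' Screening ledger
#'
#' Integer bookkeeping of subject enrolment: how many were screened, how
#' many excluded for each labelled reason, and how many dropped for
#' missing questionnaire answers.
#'
#' @param screened number screened.
#' @param exclusions named integer vector of exclusion counts by reason.
#' @param missing_questionnaire subjects dropped for incomplete answers.
#' @return An object of class `screening_ledger`.
#' @export
screening_ledger <- function(screened, exclusions = integer(), missing_questionnaire = 0L) {
  screened <- as.integer(screened)
  exclusions <- vapply(exclusions, as.integer, integer(1))
  missing_questionnaire <- as.integer(missing_questionnaire)
  if (screened < 0 || missing_questionnaire < 0 || any(exclusions < 0)) {
    stop("screening ledger counts must be non-negative")
  }
  structure(
    list(
      screened = screened, exclusions = exclusions,
      missing_questionnaire = missing_questionnaire
    ),
    class = "screening_ledger"
  )
}

#' @export
print.screening_ledger <- function(x, ...) {
  cat("<screening_ledger>", x$screened, "screened\n")
  for (nm in names(x$exclusions)) {
    cat("  -", x$exclusions[[nm]], nm, "\n")
  }
  cat("  -", x$missing_questionnaire, "missing questionnaire answers\n")
  cat("  =", apply_eligibility(x), "eligible\n")
  invisible(x)
}

#' Count eligible subjects from a screening ledger
#'
#' `eligible = screened - sum(exclusions) - missing_questionnaire`; the
#' arithmetic is exact integer bookkeeping and a negative result means
#' the ledger is internally inconsistent.
#'
#' @param ledger a [screening_ledger()].
#' @param expected optional expected total; a mismatch is an error.
#' @return Integer count of eligible subjects.
#' @export
apply_eligibility <- function(ledger, expected = NULL) {
  stopifnot(inherits(ledger, "screening_ledger"))
  n <- ledger$screened - sum(ledger$exclusions) - ledger$missing_questionnaire
  if (n < 0) {
    stop(
      "inconsistent screening ledger: exclusions (",
      sum(ledger$exclusions) + ledger$missing_questionnaire,
      ") exceed screened (", ledger$screened, ")"
    )
  }
  if (!is.null(expected) && n != expected) {
    stop("ledger yields ", n, " eligible subjects, expected ", expected)
  }
  as.integer(n)
}

#' Flag eligibility by age
#'
#' The enrolment window is strictly between 40 and 85 years. Subjects
#' exactly on a boundary are flagged rather than silently decided.
#'
#' @param age numeric vector of ages in years.
#' @return Data frame with logical `eligible` and `boundary` columns.
#' @export
age_eligibility <- function(age) {
  data.frame(
    eligible = age > 40 & age < 85,
    boundary = age %in% c(40, 85)
  )
}

#' Standardize cohort variables
#'
#' Centres and scales each listed variable to mean 0 and variance 1, the
#' pre-analysis transform applied before structural-equation modelling.
#' Binary and ordinal variables are standardized like continuous ones.
#' Rows with a missing value in any listed variable are dropped
#' (listwise deletion) with the count recorded.
#'
#' @param cohort data frame.
#' @param vars character vector of column names to standardize.
#' @param sd_type `"sample"` (divisor `n - 1`, default) or
#'   `"population"` (divisor `n`). Model chi-square and fit indices are
#'   invariant to the choice; estimates rescale by a known factor.
#' @return A list with `data` (the standardized table), `transform`
#'   (per-variable mean and sd, for inverse mapping) and `n_dropped`.
#' @export
standardize_cohort <- function(cohort, vars, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(vars, names(cohort))
  if (length(miss)) {
    stop("variable(s) absent from cohort: ", paste(miss, collapse = ", "))
  }
  keep <- stats::complete.cases(cohort[vars])
  out <- cohort[keep, , drop = FALSE]
  n <- nrow(out)
  tf <- lapply(vars, function(v) {
    x <- out[[v]]
    if (!is.numeric(x)) stop("variable ", v, " is not numeric")
    m <- mean(x)
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((n - 1) / n)
    if (!is.finite(s) || s == 0) {
      stop("variable ", v, " has zero variance; cannot standardize")
    }
    out[[v]] <<- (x - m) / s
    c(mean = m, sd = s)
  })
  names(tf) <- vars
  list(
    data = out,
    transform = do.call(rbind, tf),
    n_dropped = sum(!keep)
  )
}
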