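#' Model specification for the falls and injurious-falls analyses
#'
#' Builds the two-latent path model used throughout the package. A
#' 'Glaucomatous Damage' factor (`damage`, variance fixed to 1) drives
#' seven visual indicators: the four regional mean total deviations of
#' the integrated field, the whole-field IVF mean deviation, and
#' better- and worse-eye visual acuity. A 'Risk of Falling' construct
#' (`risk`) is regressed on age, gender, BMI, sleep-aid use, sedative
#' use, walking minutes per day, diabetes, hypertension and the damage
#' factor, and is attached to its single binary outcome indicator with
#' loading fixed to 1 and indicator residual fixed to 0 (a MIMIC-style
#' single-indicator latent). All variables are expected to be
#' standardized beforehand.
#'
#' @param outcome name of the outcome indicator column (`"fall"` or
#'   `"injurious_fall"`).
#' @param direct_va_paths also add direct regressions of `risk` on
#'   better- and worse-eye VA (an alternative reading of the path
#'   diagram in which the VA coefficients are structural rather than
#'   measurement loadings).
#' @return A [sem_model()].
#' @export
falls_model <- function(outcome = "fall", direct_va_paths = FALSE) {
  spec <- c(
    "damage =~ mtd_sup_periph + mtd_sup_cent + mtd_inf_cent + mtd_inf_periph + ivf_md + va_better + va_worse",
    paste0("risk =~ 1*", outcome),
    paste0(outcome, " ~~ 0*", outcome),
    "risk ~ age + gender + bmi + sleep_aid + sedative + walking_min + diabetes + hypertension + damage"
  )
  if (direct_va_paths) {
    spec <- c(spec, "risk ~ va_better + va_worse")
  }
  sem_model(spec)
}

#' The SEM covariates and indicators
#'
#' Column names of the variables entering the falls models, in the
#' order indicators, covariates, outcome.
#'
#' @param outcome outcome column name.
#' @return Character vector of 16 column names.
#' @export
sem_variables <- function(outcome = "fall") {
  c(
    "mtd_sup_periph", "mtd_sup_cent", "mtd_inf_cent", "mtd_inf_periph",
    "ivf_md", "va_better", "va_worse",
    "age", "gender", "bmi", "sleep_aid", "sedative", "walking_min",
    "diabetes", "hypertension", outcome
  )
}

#' Fit the falls or injurious-falls SEM to a cohort
#'
#' Standardizes every model variable (mean 0, variance 1) within the
#' analysis sample, builds the [falls_model()] specification and fits
#' it by [fit_ml()]. For `outcome = "injurious_fall"` the analysis
#' sample is restricted to fallers, mirroring the two-stage design:
#' risk factors for falling among all subjects, risk factors for injury
#' among those who fell. Coefficients whose Wald 95\% CI excludes zero
#' are flagged significant.
#'
#' @param cohort data frame containing [sem_variables()] plus `fall`.
#' @param outcome `"fall"` or `"injurious_fall"`.
#' @param direct_va_paths see [falls_model()].
#' @param sd_type standardization convention, see
#'   [standardize_cohort()].
#' @param ... passed to [fit_ml()] (e.g. `se = FALSE`).
#' @return A `sem_fit`, with the analysis sample size in `$N` and the
#'   outcome recorded in `$outcome`.
#' @export
fit_falls_sem <- function(cohort, outcome = c("fall", "injurious_fall"),
                          direct_va_paths = FALSE, sd_type = "sample", ...) {
  outcome <- match.arg(outcome)
  data <- cohort
  if (outcome == "injurious_fall") {
    if (!"fall" %in% names(data)) stop("cohort lacks the fall column")
    data <- data[data$fall == 1, , drop = FALSE]
  }
  vars <- sem_variables(outcome)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("cohort lacks variable(s): ", paste(miss, collapse = ", "))
  }
  if (length(unique(data[[outcome]])) < 2) {
    stop("degenerate outcome: ", outcome, " is constant in the analysis sample")
  }
  if (nrow(data) <= length(vars)) {
    stop(
      "analysis sample (", nrow(data), ") is not larger than the ",
      length(vars), " observed variables"
    )
  }
  std <- standardize_cohort(data, vars, sd_type = sd_type)
  model <- falls_model(outcome, direct_va_paths = direct_va_paths)
  fit <- fit_sem(model, std$data, ...)
  fit$outcome <- outcome
  fit$n_dropped <- std$n_dropped
  fit
}
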