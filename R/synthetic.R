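#' Configuration of the synthetic cohort generator
#'
#' Defines the ground truth of the generative model the package is
#' tested against: a standard-normal 'glaucomatous damage' factor per
#' subject drives the seven visual indicators through configured
#' loadings, while a latent fall-risk score combines the standardized
#' systemic covariates and the damage factor through configured
#' structural coefficients. Loadings follow the damage-severity sign
#' convention (more damage = lower total deviation, higher logMAR VA).
#'
#' Default truths: strong regional loadings (visual-field regions -0.85
#' / -0.80, whole-field -0.90), the published VA estimates 0.11
#' (better eye) and 0.14 (worse eye) as measurement truths, and for the
#' injury coefficients the published significant estimates — gender 0.36
#' and damage-to-risk 0.33, whose product with the inferior-peripheral
#' loading (-0.85 x 0.33) reproduces the published -0.28 association
#' between inferior-peripheral field loss and injurious falls; all other
#' structural coefficients 0. Demographic marginals follow the study
#' cohort (n 365, ~15\% fallers, ~40\% of fallers injured, age 64 +- 11,
#' BMI 22.4 +- 3, female fraction 0.425, diabetes 14.5\%, hypertension
#' 30.4\%, sedative 2.7\%, sleep aid 3.0\%).
#'
#' Structural truths are interpreted on the scale the analysis model
#' estimates — the linear projection of the standardized binary outcome
#' on the standardized inputs. Thresholding a latent score attenuates
#' linear associations (by roughly
#' `c = dnorm(qnorm(1 - p)) / sqrt(p (1 - p))`, see
#' [fall_scale_attenuation()]), so the generator solves the exact
#' projection equations (closed-form for normal and binary inputs) for
#' the latent coefficients that make the configured truths precisely
#' what a linear analysis of the thresholded indicator recovers.
#'
#' @param n_subjects cohort size.
#' @param seed integer seed; mandatory, every draw is reproducible.
#' @param loadings named vector of 7 measurement truths.
#' @param fall_coefs,injury_coefs named vectors of 9 structural truths
#'   (`age`, `gender`, `bmi`, `sleep_aid`, `sedative`, `walking_min`,
#'   `diabetes`, `hypertension`, `damage`).
#' @param faller_fraction,injury_fraction outcome rates (injury among
#'   fallers).
#' @param mode `"factor"` (default): each SEM indicator gets its own
#'   residual, the standard factor model; `"pipeline"`: the indicator
#'   columns are computed from the generated monocular fields through
#'   [integrate_vf()]/[summarize_ivf()], making the whole-field MD an
#'   exact linear combination of the regional means and exercising the
#'   singular-covariance ridge path in [fit_ml()].
#' @param marginals list of demographic marginal parameters; see
#'   defaults in the source.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 365, seed,
                             loadings = c(
                               mtd_sup_periph = -0.85, mtd_sup_cent = -0.80,
                               mtd_inf_cent = -0.80, mtd_inf_periph = -0.85,
                               ivf_md = -0.90, va_better = 0.11, va_worse = 0.14
                             ),
                             fall_coefs = c(
                               age = 0, gender = 0, bmi = 0, sleep_aid = 0,
                               sedative = 0, walking_min = 0, diabetes = 0,
                               hypertension = 0, damage = 0.20
                             ),
                             injury_coefs = c(
                               age = 0, gender = 0.36, bmi = 0, sleep_aid = 0,
                               sedative = 0, walking_min = 0, diabetes = 0,
                               hypertension = 0, damage = 0.33
                             ),
                             faller_fraction = 0.15, injury_fraction = 0.4,
                             mode = c("factor", "pipeline"),
                             marginals = list()) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("synthetic_config requires an explicit seed")
  defaults <- list(
    age_mean = 64.4, age_sd = 10.6,
    bmi_mean = 22.4, bmi_sd = 3.0,
    height_mean = 160, height_sd = 8,
    female_p = 155 / 365, diabetes_p = 53 / 365, hypertension_p = 111 / 365,
    sedative_p = 10 / 365, sleep_aid_p = 11 / 365,
    walking_mean = 84.8, walking_sd = 94.7,
    smoking_p = c(never = 228, previous = 92, current = 45) / 365,
    alcohol_p = c(never = 182, sometimes = 98, daily = 85) / 365,
    va_mean = 0.01, va_sd = 0.03, va_floor = -0.1,
    mtd_mean = c(
      mtd_sup_periph = -2.6, mtd_sup_cent = -2.2,
      mtd_inf_cent = -1.7, mtd_inf_periph = -1.9, ivf_md = -2.1
    ),
    mtd_sd = c(
      mtd_sup_periph = 4.5, mtd_sup_cent = 4.2,
      mtd_inf_cent = 3.6, mtd_inf_periph = 3.9, ivf_md = 3.8
    ),
    monocular_offset = -1.5, # eyes are individually worse than the IVF
    eye_noise_sd = 0.3, region_noise_sd = 0.3, point_noise_sd = 1.5
  )
  marginals <- utils::modifyList(defaults, marginals)
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    loadings = loadings, fall_coefs = fall_coefs,
    injury_coefs = injury_coefs,
    faller_fraction = faller_fraction, injury_fraction = injury_fraction,
    mode = mode, marginals = marginals
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_subjects >= 2,
      faller_fraction > 0, faller_fraction < 1,
      injury_fraction > 0, injury_fraction < 1,
      all(abs(loadings) < 1),
      marginals$age_sd > 0, marginals$bmi_sd > 0, marginals$va_sd > 0,
      all(marginals$mtd_sd > 0), marginals$point_noise_sd > 0
    )
    for (nm in c("fall", "injury")) {
      coefs <- if (nm == "fall") fall_coefs else injury_coefs
      frac <- if (nm == "fall") faller_fraction else injury_fraction
      c_att <- fall_scale_attenuation(frac)
      if (sum((coefs / c_att)^2) >= 1) {
        stop(
          "infeasible ", nm, " coefficients: de-attenuated truths imply ",
          "a latent-score variance above 1"
        )
      }
    }
  })
  invisible(cfg)
}

#' Attenuation factor of a thresholded latent score
#'
#' The linear association between a standardized input and the
#' standardized indicator `1{score > threshold}` of a unit-variance
#' latent score is the input's latent coefficient times
#' `dnorm(qnorm(1 - p)) / sqrt(p (1 - p))`, where `p` is the event
#' rate. Used by the generator to place configured truths on the
#' observable scale.
#'
#' @param p event fraction in (0, 1).
#' @return The attenuation factor (about 0.65 at p = 0.15).
#' @export
fall_scale_attenuation <- function(p) {
  stopifnot(p > 0, p < 1)
  stats::dnorm(stats::qnorm(1 - p)) / sqrt(p * (1 - p))
}

draw_binary <- function(n, p) as.integer(stats::runif(n) < p)

# standardize against the generator's theoretical marginals
theoretical_z <- function(x, mean, sd) (x - mean) / sd

# Exact calibration of the latent-score coefficients.
#
# Targets are the linear projections of the standardized binary outcome
# on the standardized inputs. For a unit-variance latent score
# thresholded at tau = qnorm(1 - p), the projection implied by latent
# coefficients g is, in closed form,
#   normal input:  beta_k = g_k phi(tau)            / sqrt(p(1-p))
#   binary input:  beta_k = sum_v P(v) z_v P(R > tau - g_k z_v)
#                           / sqrt(p(1-p)),  R ~ N(0, 1 - g_k^2)
# (the remaining score R is normal because every other nonzero
# contribution is). The fixed point g <- g * target/beta(g) converges in
# a handful of iterations and makes the configured truths exactly what
# a linear analysis of the thresholded indicator recovers.
calibrate_risk_coefs <- function(targets, binary_p, frac, tol = 1e-10, max_iter = 100) {
  sd_fall <- sqrt(frac * (1 - frac))
  tau <- stats::qnorm(1 - frac)
  nz <- which(targets != 0)
  g <- targets / fall_scale_attenuation(frac) # good starting point
  if (!length(nz)) return(g)
  implied <- function(g) {
    vapply(nz, function(k) {
      gk <- g[k]
      s_r <- sqrt(max(1 - gk^2, 1e-12))
      pk <- binary_p[k]
      if (is.na(pk)) {
        gk * stats::dnorm(tau) / sd_fall
      } else {
        z1 <- (1 - pk) / sqrt(pk * (1 - pk))
        z0 <- -pk / sqrt(pk * (1 - pk))
        cv <- pk * z1 * stats::pnorm((tau - gk * z1) / s_r, lower.tail = FALSE) +
          (1 - pk) * z0 * stats::pnorm((tau - gk * z0) / s_r, lower.tail = FALSE)
        cv / sd_fall
      }
    }, numeric(1))
  }
  for (it in seq_len(max_iter)) {
    beta <- implied(g)
    if (any(!is.finite(beta)) || any(beta == 0 & targets[nz] != 0)) {
      stop("infeasible outcome coefficients: calibration diverged")
    }
    g_new <- g
    g_new[nz] <- g[nz] * targets[nz] / beta
    if (sum(g_new[nz]^2) >= 1) {
      stop(
        "infeasible outcome coefficients: de-attenuated truths imply a ",
        "latent-score variance above 1"
      )
    }
    delta <- max(abs(g_new - g))
    g <- g_new
    if (delta < tol) break
  }
  g
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from the configured generative model: the damage
#' factor, the visual indicators, per-eye 52-point monocular fields
#' whose regional means are exact (region-level structure plus
#' re-centred point noise), independent demographic covariates from the
#' configured marginals, and fall / injurious-fall indicators obtained
#' by thresholding latent risk scores at the empirical quantile that
#' hits the configured outcome fractions exactly.
#'
#' @param config a [synthetic_config()].
#' @param fields generate the per-eye 52-point monocular fields
#'   (default). Simulation studies that only exercise the cohort-level
#'   model can pass `FALSE` to skip them; the monocular mean-deviation
#'   columns are then `NA`. Ignored (always generated) in `"pipeline"`
#'   mode, where the indicator columns come from the fields.
#' @return A list with `cohort` (one row per subject, every column of
#'   the subject record), `fields` (list of [monocular_vf()], two per
#'   subject, or `NULL` when skipped), `latent` (the true factor and
#'   risk scores, for recovery experiments) and `config`.
#' @export
generate_cohort <- function(config, fields = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  mg <- config$marginals
  lam <- config$loadings

  damage <- stats::rnorm(n)

  # --- demographic covariates (independent draws from the marginals)
  age <- stats::rnorm(n, mg$age_mean, mg$age_sd)
  gender <- draw_binary(n, mg$female_p) # female = 1
  bmi <- stats::rnorm(n, mg$bmi_mean, mg$bmi_sd)
  height <- stats::rnorm(n, mg$height_mean, mg$height_sd)
  weight <- bmi * (height / 100)^2
  diabetes <- draw_binary(n, mg$diabetes_p)
  hypertension <- draw_binary(n, mg$hypertension_p)
  sedative <- draw_binary(n, mg$sedative_p)
  sleep_aid <- draw_binary(n, mg$sleep_aid_p)
  walking_min <- stats::rgamma(
    n,
    shape = (mg$walking_mean / mg$walking_sd)^2,
    scale = mg$walking_sd^2 / mg$walking_mean
  )
  smoking <- sample(names(mg$smoking_p), n, replace = TRUE, prob = mg$smoking_p)
  alcohol <- sample(names(mg$alcohol_p), n, replace = TRUE, prob = mg$alcohol_p)
  fear_of_falling <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))

  # --- visual acuity (logMAR, floored truncated normal, skew toward 0)
  indicator_draw <- function(l) l * damage + sqrt(1 - l^2) * stats::rnorm(n)
  va_a <- pmax(mg$va_floor, mg$va_mean + mg$va_sd * indicator_draw(lam[["va_better"]]))
  va_b <- pmax(mg$va_floor, mg$va_mean + mg$va_sd * indicator_draw(lam[["va_worse"]]))
  va_better <- pmin(va_a, va_b)
  va_worse <- pmax(va_a, va_b)
  right_is_better <- draw_binary(n, 0.5)
  va_right <- ifelse(right_is_better == 1, va_better, va_worse)
  va_left <- ifelse(right_is_better == 1, va_worse, va_better)

  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, gender = gender, height = height, weight = weight,
    va_right = va_right, va_left = va_left,
    diabetes = diabetes, hypertension = hypertension,
    sedative = sedative, sleep_aid = sleep_aid,
    walking_min = walking_min, smoking = smoking, alcohol = alcohol,
    fear_of_falling = fear_of_falling,
    stringsAsFactors = FALSE
  )
  cohort <- derive_variables(cohort)

  # --- SEM indicator columns (factor mode: one residual per indicator;
  # pipeline mode overwrites them from the generated fields below)
  for (v in c("mtd_sup_periph", "mtd_sup_cent", "mtd_inf_cent", "mtd_inf_periph", "ivf_md")) {
    cohort[[v]] <- mg$mtd_mean[[v]] + mg$mtd_sd[[v]] * indicator_draw(lam[[v]])
  }

  # --- outcomes by thresholded latent risk
  z_inputs <- cbind(
    age = theoretical_z(age, mg$age_mean, mg$age_sd),
    gender = theoretical_z(gender, mg$female_p, sqrt(mg$female_p * (1 - mg$female_p))),
    bmi = theoretical_z(bmi, mg$bmi_mean, mg$bmi_sd),
    sleep_aid = theoretical_z(sleep_aid, mg$sleep_aid_p, sqrt(mg$sleep_aid_p * (1 - mg$sleep_aid_p))),
    sedative = theoretical_z(sedative, mg$sedative_p, sqrt(mg$sedative_p * (1 - mg$sedative_p))),
    walking_min = theoretical_z(walking_min, mg$walking_mean, mg$walking_sd),
    diabetes = theoretical_z(diabetes, mg$diabetes_p, sqrt(mg$diabetes_p * (1 - mg$diabetes_p))),
    hypertension = theoretical_z(hypertension, mg$hypertension_p, sqrt(mg$hypertension_p * (1 - mg$hypertension_p))),
    damage = damage
  )
  binary_p <- c(
    age = NA, gender = mg$female_p, bmi = NA, sleep_aid = mg$sleep_aid_p,
    sedative = mg$sedative_p, walking_min = NA, diabetes = mg$diabetes_p,
    hypertension = mg$hypertension_p, damage = NA
  )
  risk_score <- function(coefs, frac) {
    g <- calibrate_risk_coefs(
      coefs[colnames(z_inputs)], binary_p[colnames(z_inputs)], frac
    )
    resid_sd <- sqrt(1 - sum(g^2))
    drop(z_inputs %*% g) + resid_sd * stats::rnorm(n)
  }
  fall_risk <- risk_score(config$fall_coefs, config$faller_fraction)
  k_fall <- round(config$faller_fraction * n)
  fall <- as.integer(rank(-fall_risk, ties.method = "first") <= k_fall)

  injury_risk <- risk_score(config$injury_coefs, config$injury_fraction)
  k_inj <- round(config$injury_fraction * k_fall)
  injurious_fall <- integer(n)
  fallers <- which(fall == 1)
  top_inj <- fallers[rank(-injury_risk[fallers], ties.method = "first") <= k_inj]
  injurious_fall[top_inj] <- 1L

  cohort$fall <- fall
  cohort$injurious_fall <- injurious_fall

  # --- monocular fields, anchored to the same damage draw; a separate
  # seeded stream so cohort-level draws are identical with fields off
  if (config$mode == "pipeline") fields <- TRUE
  fields_out <- NULL
  if (fields) {
    set.seed(config$seed + 1000003L)
    fields_out <- vector("list", 2 * n)
    grid <- vf_grid("right")
    lab <- region_labels(grid)
    regions <- c("sup_periph", "sup_cent", "inf_cent", "inf_periph")
    reg_lam <- lam[paste0("mtd_", regions)] / max(abs(lam[paste0("mtd_", regions)]))
    md_right <- numeric(n)
    md_left <- numeric(n)
    for (s in seq_len(n)) {
      for (eye in c("left", "right")) {
        eye_shift <- stats::rnorm(1, 0, mg$eye_noise_sd)
        td <- numeric(nrow(grid))
        for (r in regions) {
          mu_r <- mg$mtd_mean[[paste0("mtd_", r)]] + mg$monocular_offset
          sd_r <- mg$mtd_sd[[paste0("mtd_", r)]]
          z <- reg_lam[[paste0("mtd_", r)]] * damage[s] + eye_shift +
            stats::rnorm(1, 0, mg$region_noise_sd)
          m_er <- mu_r + sd_r * z
          pts <- lab == r
          noise <- stats::rnorm(sum(pts), 0, mg$point_noise_sd)
          td[pts] <- m_er + noise - mean(noise) # regional mean exact
        }
        td <- pmin(pmax(td, -40), 15)
        g <- grid
        if (eye == "left") g$x <- -g$x
        f <- monocular_vf(cohort$subject_id[s], eye, data.frame(x = g$x, y = g$y, td = td))
        fields_out[[2 * (s - 1) + if (eye == "left") 1 else 2]] <- f
        if (eye == "right") md_right[s] <- mean(td) else md_left[s] <- mean(td)
      }
    }
    cohort$md_right <- md_right
    cohort$md_left <- md_left
    cohort$md_better <- pmax(md_right, md_left)
    cohort$md_worse <- pmin(md_right, md_left)
    if (config$mode == "pipeline") {
      ivf <- summarize_cohort_ivf(fields_out)
      i <- match(cohort$subject_id, ivf$subject_id)
      for (v in c("mtd_sup_periph", "mtd_sup_cent", "mtd_inf_cent", "mtd_inf_periph", "ivf_md")) {
        cohort[[v]] <- ivf[[v]][i]
      }
    }
  } else {
    cohort$md_right <- cohort$md_left <- NA_real_
    cohort$md_better <- cohort$md_worse <- NA_real_
  }

  list(
    cohort = cohort,
    fields = fields_out,
    latent = data.frame(
      subject_id = cohort$subject_id, damage = damage,
      fall_risk = fall_risk, injury_risk = injury_risk
    ),
    config = config
  )
}

#' Implied loadings of the ordered visual-acuity pair
#'
#' The generator draws better- and worse-eye VA as factor indicators
#' with the configured loadings and then orders the pair per subject
#' (better = min, worse = max on the logMAR scale). Ordering two
#' jointly normal indicators changes their moments in closed form: with
#' standardized pre-ordering draws correlated `r = lb lw`, the ordered
#' variables have `|E[min]| = E[max] = sqrt((1 - r) / pi)`, variance
#' `1 - (1 - r)/pi`, and covariance with the factor `(lb + lw)/2` each
#' (the antisymmetric part `|A - B|` is uncorrelated with the factor).
#' The implied standardized loading of both ordered indicators is
#' therefore `(lb + lw) / 2 / sqrt(1 - (1 - r)/pi)` — the truth value
#' recovery experiments should compare against.
#'
#' @param config a [synthetic_config()].
#' @return List with `loading` (implied standardized loading, same for
#'   both), `delta` (mean shift of max), `sd` (sd of each ordered
#'   variable on the standardized pre-ordering scale).
#' @export
implied_va_loadings <- function(config) {
  lb <- config$loadings[["va_better"]]
  lw <- config$loadings[["va_worse"]]
  r <- lb * lw
  delta <- sqrt((1 - r) / pi)
  s <- sqrt(1 - delta^2)
  list(loading = (lb + lw) / 2 / s, delta = delta, sd = s)
}

#' Standardize a generated cohort by its population parameters
#'
#' Standardizes the SEM variables of a synthetic cohort using the
#' generator's own marginal constants (population means and sds) rather
#' than per-sample moments. Per-sample standardization pins every
#' sample variance to exactly 1, which makes ML standard errors of
#' loading-type parameters conservative; standardizing by the known
#' population constants leaves the sampling variability intact, so
#' Wald coverage of the engine can be assessed at its nominal level.
#' Intended for simulation studies; the analysis pipeline itself uses
#' [standardize_cohort()] on real data, where population constants are
#' unknown.
#'
#' @param generated result of [generate_cohort()].
#' @return The cohort data frame with the SEM variable columns replaced
#'   by their population-standardized versions.
#' @export
standardize_theoretical <- function(generated) {
  cohort <- generated$cohort
  cfg <- generated$config
  mg <- cfg$marginals
  z <- function(v, m, s) (cohort[[v]] - m) / s
  for (v in c("mtd_sup_periph", "mtd_sup_cent", "mtd_inf_cent", "mtd_inf_periph", "ivf_md")) {
    cohort[[v]] <- z(v, mg$mtd_mean[[v]], mg$mtd_sd[[v]])
  }
  va <- implied_va_loadings(cfg)
  cohort$va_better <- z("va_better", mg$va_mean - va$delta * mg$va_sd, va$sd * mg$va_sd)
  cohort$va_worse <- z("va_worse", mg$va_mean + va$delta * mg$va_sd, va$sd * mg$va_sd)
  cohort$age <- z("age", mg$age_mean, mg$age_sd)
  cohort$bmi <- z("bmi", mg$bmi_mean, mg$bmi_sd)
  cohort$walking_min <- z("walking_min", mg$walking_mean, mg$walking_sd)
  binary_marg <- c(
    gender = "female_p", sleep_aid = "sleep_aid_p", sedative = "sedative_p",
    diabetes = "diabetes_p", hypertension = "hypertension_p"
  )
  for (nm in names(binary_marg)) {
    p <- mg[[binary_marg[[nm]]]]
    cohort[[nm]] <- (cohort[[nm]] - p) / sqrt(p * (1 - p))
  }
  p_fall <- cfg$faller_fraction
  cohort$fall <- (cohort$fall - p_fall) / sqrt(p_fall * (1 - p_fall))
  p_inj <- cfg$injury_fraction
  cohort$injurious_fall <- (cohort$injurious_fall - p_inj) / sqrt(p_inj * (1 - p_inj))
  cohort
}

#' Screening ledger with the study's enrolment counts
#'
#' The default fixture: 617 screened, the itemised exclusion reasons
#' summing to 246, and 6 subjects dropped for incomplete questionnaire
#' answers, which yields 365 eligible subjects.
#'
#' @param screened,exclusions,missing_questionnaire overrides of the
#'   default counts.
#' @return A [screening_ledger()].
#' @export
generate_screening_ledger <- function(screened = 617,
                                      exclusions = c(
                                        younger_than_40 = 28, older_than_85 = 25,
                                        refusal = 10, dementia = 3, low_va = 24,
                                        secondary_glaucoma = 62, other_glaucoma = 16,
                                        retinal_detachment = 21, diabetic_retinopathy = 36,
                                        bullous_keratopathy = 2, amd = 2,
                                        other_ocular_disease = 1, cannot_walk_unaided = 0,
                                        walks_with_cane = 16
                                      ),
                                      missing_questionnaire = 6) {
  screening_ledger(screened, exclusions, missing_questionnaire)
}

#' Write a generated cohort to CSV files
#'
#' Emits the cohort table and the monocular visual-field table in the
#' dialects read by [read_vf_table()] and consumed by the pipeline.
#'
#' @param generated result of [generate_cohort()].
#' @param cohort_path,vf_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(generated, cohort_path, vf_path) {
  utils::write.csv(generated$cohort, cohort_path, row.names = FALSE)
  write_vf_table(generated$fields, vf_path)
  invisible(c(cohort = cohort_path, vf = vf_path))
}
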