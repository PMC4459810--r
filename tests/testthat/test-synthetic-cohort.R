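test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_subjects = 40, seed = 7)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$fields, g2$fields)
  # cohort-level draws are unchanged when fields are skipped
  g3 <- generate_cohort(cfg, fields = FALSE)
  expect_null(g3$fields)
  expect_identical(
    g1$cohort[setdiff(names(g1$cohort), c("md_right", "md_left", "md_better", "md_worse"))],
    g3$cohort[setdiff(names(g3$cohort), c("md_right", "md_left", "md_better", "md_worse"))]
  )
  # a different seed changes the draw
  expect_false(identical(
    generate_cohort(synthetic_config(n_subjects = 40, seed = 8))$cohort$age,
    g1$cohort$age
  ))
  expect_error(synthetic_config(n_subjects = 40), "seed")
})

test_that("outcome fractions hit their configured targets exactly", {
  for (seed in 1:5) {
    gen <- generate_cohort(synthetic_config(seed = seed), fields = FALSE)
    expect_equal(sum(gen$cohort$fall), round(0.15 * 365)) # 55 fallers
    expect_equal(sum(gen$cohort$injurious_fall), round(0.4 * 55)) # 22 injured
    # injury implies fall
    expect_true(all(gen$cohort$fall[gen$cohort$injurious_fall == 1] == 1))
  }
})

test_that("subject records are internally consistent", {
  gen <- generate_cohort(synthetic_config(n_subjects = 60, seed = 11))
  coh <- gen$cohort
  expect_true(all(coh$va_better <= coh$va_worse))
  expect_true(all(coh$va_better == pmin(coh$va_right, coh$va_left)))
  expect_true(all(coh$md_better >= coh$md_worse))
  expect_equal(coh$bmi, coh$weight / (coh$height / 100)^2, tolerance = 1e-12)
  expect_true(all(coh$va_better >= -0.1)) # logMAR floor
  expect_true(all(coh$walking_min >= 0))
  expect_true(all(coh$gender %in% 0:1))
})

test_that("generated fields satisfy every integration invariant", {
  gen <- generate_cohort(synthetic_config(n_subjects = 25, seed = 13))
  expect_length(gen$fields, 50)
  summaries <- summarize_cohort_ivf(gen$fields)
  expect_equal(nrow(summaries), 25)
  # IVF dominates each monocular field
  ids <- vapply(gen$fields, `[[`, character(1), "subject_id")
  eyes <- vapply(gen$fields, `[[`, character(1), "eye")
  for (s in c(1, 12, 25)) {
    id <- sprintf("S%03d", s)
    l <- gen$fields[[which(ids == id & eyes == "left")]]
    r <- gen$fields[[which(ids == id & eyes == "right")]]
    ivf <- integrate_vf(l, r)
    expect_true(all(ivf$points$td >= r$points$td))
    expect_gte(mean(ivf$points$td), mean(l$points$td))
    expect_gte(mean(ivf$points$td), mean(r$points$td))
    # whole-field summary equals the weighted regional mean
    sm <- summarize_ivf(ivf)
    expect_equal(
      sm$ivf_md,
      (18 * sm$mtd_sup_periph + 8 * sm$mtd_sup_cent + 8 * sm$mtd_inf_cent + 18 * sm$mtd_inf_periph) / 52
    )
  }
})

test_that("indicator correlations with the latent reproduce the loadings", {
  cfg <- synthetic_config(n_subjects = 1e5, seed = 17)
  gen <- generate_cohort(cfg, fields = FALSE)
  d <- gen$latent$damage
  # factor-mode indicators: population correlation equals the loading
  for (v in c("mtd_sup_periph", "mtd_sup_cent", "mtd_inf_cent", "mtd_inf_periph", "ivf_md")) {
    expect_equal(cor(gen$cohort[[v]], d), cfg$loadings[[v]], tolerance = 0.02)
  }
  # ordered VA pair: correlation equals the closed-form implied loading
  iv <- implied_va_loadings(cfg)
  expect_lt(abs(cor(gen$cohort$va_better, d) - iv$loading), 0.01)
  expect_lt(abs(cor(gen$cohort$va_worse, d) - iv$loading), 0.01)

  # configured structural truth equals the projection of the
  # standardized outcome on the standardized input (exact calibration)
  fig3 <- c(
    age = 0, gender = 0.36, bmi = 0, sleep_aid = 0, sedative = 0,
    walking_min = 0, diabetes = 0, hypertension = 0, damage = 0.33
  )
  gen2 <- generate_cohort(
    synthetic_config(n_subjects = 2e5, seed = 19, fall_coefs = fig3),
    fields = FALSE
  )
  z_g <- with(gen2$cohort, (gender - mean(gender)) / sd(gender))
  z_f <- with(gen2$cohort, (fall - mean(fall)) / sd(fall))
  expect_lt(abs(cov(z_g, z_f) - 0.36), 0.015)
  expect_lt(abs(cov(gen2$latent$damage, z_f) - 0.33), 0.015)

  # all-null coefficients leave the outcome unassociated
  null_cfg <- synthetic_config(
    n_subjects = 2e5, seed = 23,
    fall_coefs = c(
      age = 0, gender = 0, bmi = 0, sleep_aid = 0, sedative = 0,
      walking_min = 0, diabetes = 0, hypertension = 0, damage = 0
    )
  )
  gen3 <- generate_cohort(null_cfg, fields = FALSE)
  expect_lt(abs(cor(gen3$cohort$gender, gen3$cohort$fall)), 0.01)
})

test_that("infeasible outcome targets are rejected at configuration", {
  expect_error(
    synthetic_config(
      seed = 1,
      fall_coefs = c(
        age = 0.5, gender = 0.5, bmi = 0.5, sleep_aid = 0, sedative = 0,
        walking_min = 0, diabetes = 0, hypertension = 0, damage = 0.5
      )
    ),
    "infeasible"
  )
})

test_that("pipeline mode routes indicators through the IVF and is singular by design", {
  gen <- generate_cohort(synthetic_config(n_subjects = 80, seed = 29, mode = "pipeline"))
  coh <- gen$cohort
  # whole-field MD is exactly the weighted mean of the regional columns
  expect_equal(
    coh$ivf_md,
    (18 * coh$mtd_sup_periph + 8 * coh$mtd_sup_cent + 8 * coh$mtd_inf_cent + 18 * coh$mtd_inf_periph) / 52,
    tolerance = 1e-12
  )
  # fitting therefore takes the ridge path
  fit <- fit_falls_sem(coh, "fall", se = FALSE)
  expect_true(fit$ridge)
  expect_true(is.finite(fit$chi_square))
})
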