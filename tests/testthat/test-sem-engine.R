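test_that("a just-identified factor model fits exactly with closed-form loadings", {
  dat <- make_factor_data(n = 200, seed = 42)
  S <- cov(dat)
  fit <- fit_ml(sem_model("f =~ y1 + y2 + y3"), S, 200)
  expect_equal(fit$F_ml, 0, tolerance = 1e-9)
  expect_equal(fit$chi_square, 0, tolerance = 1e-6)
  expect_equal(fit$df, 0)
  expect_true(fit$saturated)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$cfi, 1)
  # classical closed-form solution for the three loadings
  expect_equal(
    fit$estimates$estimate[fit$estimates$label == "f=~y1"],
    sqrt(S[1, 2] * S[1, 3] / S[2, 3]),
    tolerance = 1e-6
  )
  expect_equal(
    fit$estimates$estimate[fit$estimates$label == "f=~y2"],
    sqrt(S[1, 2] * S[2, 3] / S[1, 3]),
    tolerance = 1e-6
  )
  # F_ML at the optimum of a saturated model is zero iff Sigma == S
  expect_equal(implied_covariance(fit$model, fit$theta), unclass(S),
    tolerance = 1e-5, ignore_attr = TRUE
  )
})

test_that("the analytic gradient matches central differences", {
  m <- sem_model(c("f =~ 1*y1 + y2 + y3", "f ~ x"))
  set.seed(43)
  dat <- make_factor_data(n = 150, seed = 43)
  dat$x <- 0.5 * dat$y1 + rnorm(150)
  S <- cov(dat[c("y1", "y2", "y3", "x")])
  obj <- ivfsem:::sem_objective_env(m, S, determinant(S, TRUE)$modulus[1])
  theta <- ivfsem:::start_values(m, S) + runif(nrow(m$params), -0.05, 0.05)
  g_an <- obj$gr(theta)
  g_num <- vapply(seq_along(theta), function(k) {
    h <- 1e-6 * (1 + abs(theta[k]))
    up <- theta; dn <- theta
    up[k] <- up[k] + h; dn[k] <- dn[k] - h
    (obj$fn(up) - obj$fn(dn)) / (2 * h)
  }, numeric(1))
  expect_equal(g_an, g_num, tolerance = 1e-6)
})

test_that("fit indices reproduce their analytic cases", {
  # exact fit
  fi <- fit_indices(10, 10, 60, 15, 101)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  # chi2 - df = 10, df = 10, N = 101 -> RMSEA = 0.1
  expect_equal(fit_indices(20, 10, 100, 15, 101)$rmsea, 0.1)
  # model excess 5 over baseline excess 50 -> CFI = 0.9
  expect_equal(fit_indices(15, 10, 65, 15, 101)$cfi, 0.9)
  # saturated flag
  expect_true(fit_indices(0, 0, 50, 10, 100)$saturated)
  # the excess is floored at zero
  expect_equal(fit_indices(5, 10, 60, 15, 101)$rmsea, 0)
  expect_equal(fit_indices(5, 10, 60, 15, 101)$cfi, 1)
})

test_that("chi-square, RMSEA and CFI are invariant to rescaling one variable", {
  dat <- make_factor_data(n = 300, loadings = c(0.8, 0.7, 0.6, 0.5), seed = 44)
  m <- sem_model("f =~ y1 + y2 + y3 + y4")
  S <- cov(dat)
  f1 <- fit_ml(m, S, 300)
  S2 <- S
  S2[2, ] <- S2[2, ] * 10
  S2[, 2] <- S2[, 2] * 10
  f2 <- fit_ml(m, S2, 300)
  expect_equal(f2$chi_square, f1$chi_square, tolerance = 1e-6)
  expect_equal(f2$rmsea, f1$rmsea, tolerance = 1e-6)
  expect_equal(f2$cfi, f1$cfi, tolerance = 1e-6)
  # the rescaled variable's loading scales by 10, others unchanged
  expect_equal(
    f2$estimates$estimate[f2$estimates$label == "f=~y2"],
    10 * f1$estimates$estimate[f1$estimates$label == "f=~y2"],
    tolerance = 1e-5
  )
  expect_equal(
    f2$estimates$estimate[f2$estimates$label == "f=~y1"],
    f1$estimates$estimate[f1$estimates$label == "f=~y1"],
    tolerance = 1e-5
  )
})

test_that("estimates agree with the independent ML factor-analysis implementation", {
  # random one-factor models cross-checked against stats::factanal
  set.seed(45)
  for (k in 1:8) {
    p <- sample(4:7, 1)
    lam <- runif(p, 0.4, 0.9)
    n <- 400
    d <- rnorm(n)
    X <- sapply(lam, function(l) l * d + sqrt(1 - l^2) * rnorm(n))
    colnames(X) <- paste0("v", seq_len(p))
    S <- cor(X)
    fa <- factanal(covmat = S, factors = 1, n.obs = n, rotation = "none")
    fit <- fit_ml(
      sem_model(paste("f =~", paste(colnames(X), collapse = " + "))),
      S, n,
      se = FALSE
    )
    est <- fit$estimates
    expect_equal(
      abs(est$estimate[est$type == "loading"]),
      abs(as.numeric(fa$loadings)),
      tolerance = 1e-3
    )
    expect_equal(
      est$estimate[est$type == "variance"],
      as.numeric(fa$uniquenesses),
      tolerance = 1e-3
    )
    expect_equal(fit$F_ml, fa$criteria[["objective"]], tolerance = 1e-6)
  }
})

test_that("latent signs are resolved so the first loading is non-negative", {
  dat <- make_factor_data(n = 250, seed = 46)
  # flip the data so the natural solution would have negative loadings
  dat_neg <- -dat
  f_pos <- fit_sem(sem_model("f =~ y1 + y2 + y3"), dat)
  f_neg <- fit_sem(sem_model("f =~ y1 + y2 + y3"), dat_neg)
  expect_gte(f_pos$estimates$estimate[1], 0)
  expect_gte(f_neg$estimates$estimate[1], 0)
  expect_equal(f_pos$estimates$estimate, f_neg$estimates$estimate, tolerance = 1e-6)
})

test_that("Wald intervals bracket their estimates and flag zero-exclusion", {
  dat <- make_factor_data(n = 300, seed = 47)
  fit <- fit_sem(sem_model("f =~ y1 + y2 + y3"), dat)
  est <- fit$estimates
  expect_true(all(est$ci_lower <= est$estimate & est$estimate <= est$ci_upper))
  expect_true(all(est$significant == (est$ci_lower > 0 | est$ci_upper < 0)))
  # strong loadings at n = 300 are flagged
  expect_true(all(est$significant[est$type == "loading"]))
})

test_that("guards reject undersized samples and overparameterised models", {
  dat <- make_factor_data(n = 200, seed = 48)
  S <- cov(dat)
  expect_error(fit_ml(sem_model("f =~ y1 + y2 + y3"), S, 3), "must exceed")
  m_over <- sem_model(c("f =~ y1 + y2 + y3", "y1 ~~ y2", "y1 ~~ y3", "y2 ~~ y3"))
  expect_error(fit_ml(m_over, S, 200), "free parameters")
  expect_error(fit_ml(sem_model("f =~ y1 + y2 + y3"), unname(S), 200), "names")
})

test_that("a singular sample covariance takes the logged ridge path", {
  set.seed(49)
  n <- 120
  dat <- make_factor_data(n = n, loadings = c(0.8, 0.7, 0.6), seed = 49)
  dat$y4 <- (dat$y1 + dat$y2) / 2 # exact linear combination
  m <- sem_model("f =~ y1 + y2 + y3 + y4")
  # SEs are partly undefined on a ridge-regularised singular input
  fit <- suppressWarnings(fit_ml(m, cov(dat), n))
  expect_true(fit$ridge)
  expect_true(is.finite(fit$chi_square))
  # a well-conditioned covariance does not trigger it
  expect_false(fit_ml(m, cov(make_factor_data(150, c(.7, .6, .5, .4), seed = 50)), 150)$ridge)
})
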