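test_that("the model syntax parses into the expected free parameters", {
  m <- sem_model("
    # one factor, three indicators
    f =~ y1 + y2 + y3
  ")
  expect_equal(m$latents, "f")
  expect_setequal(m$obs, c("y1", "y2", "y3"))
  # 3 loadings + 3 residual variances; factor variance fixed to 1
  expect_equal(nrow(m$params), 6)
  expect_equal(sum(m$params$type == "loading"), 3)
  expect_equal(m$S["f", "f"], 1)
  expect_false(m$S_free["f", "f"])

  # fixed loading and fixed residual via the 1*/0* syntax
  m2 <- sem_model(c("risk =~ 1*fall", "fall ~~ 0*fall", "risk ~ x1 + x2"))
  expect_equal(m2$A["fall", "risk"], 1)
  expect_false(m2$A_free["fall", "risk"])
  expect_false(m2$S_free["fall", "fall"])
  expect_equal(m2$S["fall", "fall"], 0)
  # endogenous latent gets a free residual variance
  expect_true(m2$S_free["risk", "risk"])
  # exogenous observed block is saturated: 2 variances + 1 covariance
  expect_equal(sum(m2$params$matrix == "S" & m2$params$type == "covariance"), 1)

  expect_error(sem_model("a ~ b\nb ~ a"), "cyclic")
  expect_error(sem_model("f =~ y1 + oops*y2"), "cannot parse")
})

test_that("the preconfigured falls model matches the published structure", {
  m <- falls_model()
  expect_setequal(m$latents, c("damage", "risk"))
  expect_equal(length(m$obs), 16)
  # 7 loadings, 9 structural paths, 7 indicator residuals, 1 risk
  # residual, 8 exogenous variances + 28 exogenous covariances
  expect_equal(nrow(m$params), 60)
  expect_equal(sum(m$params$type == "loading"), 7)
  expect_equal(sum(m$params$type == "path"), 9)
  # moment count supports the parameterisation
  expect_lte(nrow(m$params), 16 * 17 / 2)
  # the variant with direct VA paths adds exactly two
  expect_equal(nrow(falls_model(direct_va_paths = TRUE)$params), 62)
})

test_that("implied covariance follows the factor-model algebra", {
  m <- sem_model("f =~ y1 + y2 + y3")
  th <- m$params
  # null model: all loadings zero -> Sigma is the residual diagonal
  theta <- ifelse(th$type == "loading", 0, c(0.3, 0.5, 0.7))[seq_len(nrow(th))]
  theta[th$type == "loading"] <- 0
  theta[th$type == "variance"] <- c(0.3, 0.5, 0.7)
  Sig <- implied_covariance(m, theta)
  expect_equal(Sig, diag(c(0.3, 0.5, 0.7)), ignore_attr = TRUE)

  # off-diagonals are lambda_i lambda_j with unit factor variance
  lam <- c(0.8, 0.6, 0.4)
  theta[th$type == "loading"] <- lam
  Sig <- implied_covariance(m, theta)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i != j) expect_equal(Sig[i, j], lam[i] * lam[j])
    }
  }
})

test_that("implied covariance matches a Monte-Carlo simulation oracle", {
  # small structural model: f -> y1..y3, f ~ x (scale set by the fixed
  # unit loading), simulated generatively
  m <- sem_model(c("f =~ 1*y1 + y2 + y3", "f ~ x"))
  th <- m$params
  theta <- numeric(nrow(th))
  theta[th$label == "f=~y2"] <- 0.7
  theta[th$label == "f=~y3"] <- 0.5
  theta[th$label == "f~x"] <- 0.6
  theta[th$label == "x~~x"] <- 1.5
  theta[th$label == "f~~f"] <- 0.8
  theta[th$label == "y1~~y1"] <- 0.4
  theta[th$label == "y2~~y2"] <- 0.6
  theta[th$label == "y3~~y3"] <- 0.9

  set.seed(41)
  n <- 4e5
  x <- rnorm(n, sd = sqrt(1.5))
  f <- 0.6 * x + rnorm(n, sd = sqrt(0.8))
  Y <- cbind(
    y1 = 1.0 * f + rnorm(n, sd = sqrt(0.4)),
    y2 = 0.7 * f + rnorm(n, sd = sqrt(0.6)),
    y3 = 0.5 * f + rnorm(n, sd = sqrt(0.9)),
    x = x
  )
  Sig <- implied_covariance(m, theta)
  S_mc <- cov(Y)[rownames(Sig), colnames(Sig)]
  expect_equal(Sig, S_mc, tolerance = 0.02, ignore_attr = TRUE)
  # symmetric and PSD
  expect_equal(Sig, t(Sig))
  expect_gte(min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values), 0)
})
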