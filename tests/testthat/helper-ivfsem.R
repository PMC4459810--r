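# shared fixtures, built in code

# a monocular field with constant (or supplied) td values
make_vf <- function(subject = "S1", eye = "right", td = -4) {
  g <- vf_grid(eye)
  if (length(td) == 1) td <- rep(td, nrow(g))
  monocular_vf(subject, eye, data.frame(x = g$x, y = g$y, td = td))
}

# independent Fisher oracle: enumerate all 2x2 tables with the observed
# margins and sum hypergeometric probabilities <= that of the observed
# table (point-probability rule)
fisher_enumeration_p <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small one-factor data set with known structure
make_factor_data <- function(n = 200, loadings = c(0.7, 0.6, 0.8), seed = 1) {
  set.seed(seed)
  d <- stats::rnorm(n)
  X <- sapply(loadings, function(l) l * d + sqrt(1 - l^2) * stats::rnorm(n))
  colnames(X) <- paste0("y", seq_along(loadings))
  as.data.frame(X)
}

# published contingency tables (rows: group of interest, comparison)
tables_printed <- list(
  gender_injurious = matrix(c(6, 23, 16, 10), 2), # male/female x injury+/-
  diabetes_fall = matrix(c(12, 41, 43, 269), 2),
  hypertension_fall = matrix(c(18, 93, 37, 217), 2),
  hypertension_injurious = matrix(c(8, 10, 14, 23), 2),
  sedative_fall = matrix(c(2, 8, 53, 302), 2)
)
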