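test_that("uncorrected chi-square matches the 2x2 closed form", {
  set.seed(31)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    res <- chi_square_test(tab)
    expect_equal(res$statistic, closed, tolerance = 1e-12)
    expect_equal(res$df, 1)
    # invariance to row/column permutation
    expect_equal(chi_square_test(tab[2:1, ])$p, res$p)
    expect_equal(chi_square_test(tab[, 2:1])$p, res$p)
  }
  # perfect homogeneity
  hom <- chi_square_test(matrix(10, 2, 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Fisher's exact test equals the enumeration oracle on all small tables", {
  # every 2x2 table with total <= 12
  for (n in 1:12) {
    parts <- expand.grid(a = 0:n, b = 0:n, c_ = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(c(
        parts$a[i], parts$b[i], parts$c_[i],
        n - parts$a[i] - parts$b[i] - parts$c_[i]
      ), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        expect_equal(fisher_exact_test(tab)$p, 1)
      } else {
        expect_equal(
          fisher_exact_test(tab)$p, fisher_enumeration_p(tab),
          tolerance = 1e-10
        )
      }
    }
  }
  # identical rows carry no association
  expect_equal(fisher_exact_test(matrix(c(4, 4, 7, 7), 2))$p, 1)
})

test_that("printed-table chi-square and Fisher p-values reproduce", {
  expect_equal(round(chi_square_test(tables_printed$gender_injurious)$p, 3), 0.002)
  expect_equal(round(chi_square_test(tables_printed$diabetes_fall)$p, 2), 0.10)
  expect_equal(round(chi_square_test(tables_printed$hypertension_fall)$p, 2), 0.69)
  expect_equal(round(chi_square_test(tables_printed$hypertension_injurious)$p, 2), 0.64)
  expect_equal(round(fisher_exact_test(tables_printed$sedative_fall)$p, 2), 0.65)
})

test_that("unpaired t-tests behave under Welch and Student variants", {
  x <- c(1.2, 3.4, 2.2, 4.1)
  expect_equal(unpaired_t_test(x, x)$p, 1)
  expect_equal(unpaired_t_test(x, x)$statistic, 0)
  expect_error(unpaired_t_test(1, x), "at least 2")

  # summary-statistic entry point reproduces the printed age comparison
  age <- t_test_from_summary(66.8, 11.5, 55, 64.0, 10.4, 310)
  expect_equal(round(age$p, 2), 0.10)
  # pooled-variance Student gives a different (smaller) p here
  age_s <- t_test_from_summary(66.8, 11.5, 55, 64.0, 10.4, 310, welch = FALSE)
  expect_lt(age_s$p, age$p)
  expect_equal(age_s$df, 363)

  # summary path agrees with the raw-data path
  set.seed(32)
  a <- rnorm(30, 1); b <- rnorm(40, 0.4)
  raw <- unpaired_t_test(a, b)
  summ <- t_test_from_summary(mean(a), sd(a), 30, mean(b), sd(b), 40)
  expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
  expect_equal(summ$p, raw$p, tolerance = 1e-12)
})

test_that("Welch test holds its nominal type-I error under the null", {
  set.seed(33)
  reps <- 10000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    rej[i] <- unpaired_t_test(rnorm(12), rnorm(20, sd = 2))$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("comparison tables assemble the full variable battery", {
  gen <- generate_cohort(synthetic_config(n_subjects = 120, seed = 3))
  tab <- build_comparison_table(gen$cohort, "fall")
  expect_equal(nrow(tab), 16) # n row + 15 variables
  expect_true(all(tab$p_value[-1] >= 0 & tab$p_value[-1] <= 1))
  expect_match(tab$group1[tab$variable == "ivf_md"], "\\[")
  expect_match(tab$group1[tab$variable == "diabetes"], "%")
  # group sizes in the header row partition the cohort
  expect_equal(
    as.integer(tab$group1[1]) + as.integer(tab$group0[1]),
    nrow(gen$cohort)
  )
  # degenerate grouping is an error
  coh0 <- gen$cohort
  coh0$fall <- 0
  expect_error(build_comparison_table(coh0, "fall"), "degenerate")
  # a missing variable is a named error
  expect_error(
    build_comparison_table(gen$cohort[, setdiff(names(gen$cohort), "bmi")], "fall"),
    "bmi"
  )
})
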