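#' @title Univariate group-comparison battery
#' @description Tests used in the faller/non-faller and
#'   injurious/non-injurious comparison tables: Pearson chi-square
#'   without continuity correction for categorical variables with
#'   adequate counts, Fisher's exact test for sparse binary variables,
#'   and the unpaired t-test (Welch by default) for continuous ones.
#' @name group_stats
NULL

test_result <- function(method, statistic, df, p) {
  if (!is.na(p)) p <- min(max(p, 0), 1) # guard numerical overshoot
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(
    list(method = method, statistic = statistic, df = df, p = p),
    class = "ivfsem_test"
  )
}

#' @export
print.ivfsem_test <- function(x, ...) {
  cat(
    "<", x$method, "> statistic = ",
    if (is.na(x$statistic)) "NA" else sprintf("%.4g", x$statistic),
    if (!is.na(x$df)) paste0(", df = ", sprintf("%.4g", x$df)) else "",
    ", p = ", sprintf("%.4g", x$p), "\n",
    sep = ""
  )
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction, the
#' convention that reproduces the comparison tables); the corrected
#' statistic is available behind `correct = TRUE` for sensitivity
#' analysis.
#'
#' @param tab matrix of non-negative integer counts, at least 2x2.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return An `ivfsem_test` with the statistic, `(r-1)(c-1)` degrees of
#'   freedom and the two-sided p-value.
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) == 0) stop("counts must be non-negative with a positive total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined: a row or column margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  test_result(
    if (correct) "chi-square (Yates)" else "chi-square",
    unname(ct$statistic), unname(ct$parameter), unname(ct$p.value)
  )
}

#' Fisher's exact test of a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table.
#' A table with a zero margin carries no information about association;
#' its p-value is 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return An `ivfsem_test` (degrees of freedom not applicable).
#' @export
fisher_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, ncol(tab) == 2)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(test_result("Fisher exact (degenerate margin)", NA_real_, NA_real_, 1))
  }
  ft <- stats::fisher.test(tab)
  test_result("Fisher exact", NA_real_, NA_real_, unname(ft$p.value))
}

#' Unpaired t-test
#'
#' Welch's unequal-variance t-test by default (the variant that
#' reproduces the comparison tables from their printed summaries); the
#' pooled-variance Student test is available with `welch = FALSE`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch-Satterthwaite statistic (default).
#' @return An `ivfsem_test`.
#' @export
unpaired_t_test <- function(a, b, welch = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("unpaired t-test needs at least 2 observations per group")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate but well-defined: identical constant groups
    return(test_result("Welch t", 0, length(a) + length(b) - 2, 1))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  test_result(
    if (welch) "Welch t" else "Student t",
    unname(tt$statistic), unname(tt$parameter), unname(tt$p.value)
  )
}

#' Unpaired t-test from printed summary statistics
#'
#' Recomputes the two-sample t-test from group means, standard
#' deviations and sizes — the entry point for checking published tables
#' where only summaries are available.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @param welch Welch (default) or pooled-variance Student.
#' @return An `ivfsem_test`.
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, welch = TRUE) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (welch) {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    method <- "Welch t (summary)"
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
    method <- "Student t (summary)"
  }
  t <- (mean_a - mean_b) / se
  test_result(method, t, df, 2 * stats::pt(-abs(t), df))
}

# variable plan describing the comparison-table rows: which test each
# variable gets, mirroring the table footnotes.
default_variable_plan <- function() {
  data.frame(
    variable = c(
      "age", "va_better", "va_worse", "gender", "bmi", "smoking",
      "alcohol", "diabetes", "hypertension", "sedative", "sleep_aid",
      "walking_min", "ivf_md", "md_better", "md_worse"
    ),
    test = c(
      "t", "t", "t", "chisq", "t", "chisq",
      "chisq", "chisq", "chisq", "fisher", "fisher",
      "t", "t_range", "t_range", "t_range"
    ),
    stringsAsFactors = FALSE
  )
}

summarize_continuous <- function(x, with_range = FALSE) {
  # small-scale variables (logMAR VA) need two decimals to be legible
  d <- if (max(abs(mean(x)), stats::sd(x)) < 1) 2 else 1
  s <- sprintf("%.*f ± %.*f", d, mean(x), d, stats::sd(x))
  if (with_range) s <- sprintf("%s [%.*f–%.*f]", s, d, min(x), d, max(x))
  s
}

#' Build a group-comparison table
#'
#' Assembles the univariate comparison table for a binary grouping
#' (fallers vs non-fallers, or injurious vs non-injurious fallers):
#' mean +- sd for continuous variables (with ranges for the mean
#' deviations), counts for categorical ones, and the p-value from the
#' test assigned to each variable by the plan.
#'
#' @param cohort data frame of subject records.
#' @param grouping name of a binary column (`"fall"` or
#'   `"injurious_fall"`).
#' @param plan data frame with columns `variable` and `test`
#'   (`"t"`, `"t_range"`, `"chisq"`, `"fisher"`); defaults to the
#'   standard 15-variable battery.
#' @param welch,correct options forwarded to the t and chi-square tests.
#' @return Data frame with one header row of group sizes plus one row
#'   per variable: `variable`, `group1` (grouping == 1), `group0`,
#'   `p_value`, `test`.
#' @export
build_comparison_table <- function(cohort, grouping = c("fall", "injurious_fall"),
                                   plan = default_variable_plan(),
                                   welch = TRUE, correct = FALSE) {
  grouping <- match.arg(grouping)
  if (!grouping %in% names(cohort)) stop("grouping column ", grouping, " absent")
  g <- cohort[[grouping]]
  if (!all(g %in% 0:1)) stop("grouping column must be binary 0/1")
  if (length(unique(g)) < 2) {
    stop("degenerate grouping: column ", grouping, " has a single level")
  }
  missing <- setdiff(plan$variable, names(cohort))
  if (length(missing)) {
    stop("variable(s) absent from cohort: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    v <- plan$variable[i]
    test <- plan$test[i]
    x1 <- cohort[[v]][g == 1]
    x0 <- cohort[[v]][g == 0]
    if (test %in% c("t", "t_range")) {
      res <- unpaired_t_test(x1, x0, welch = welch)
      s1 <- summarize_continuous(x1, test == "t_range")
      s0 <- summarize_continuous(x0, test == "t_range")
    } else {
      col <- cohort[[v]]
      # force both levels of binary variables so sparse subgroups keep
      # a 2x2 layout (a zero margin then falls to the p = 1 convention)
      if (all(col %in% 0:1)) col <- factor(col, levels = 0:1)
      tab <- table(factor(g, levels = c(1, 0)), col)
      res <- if (test == "fisher") {
        fisher_exact_test(tab)
      } else {
        chi_square_test(tab, correct = correct)
      }
      fmt <- function(x) {
        if (length(unique(cohort[[v]])) == 2 && all(cohort[[v]] %in% 0:1)) {
          sprintf("%d/%d = %.1f%%", sum(x == 1), length(x), 100 * mean(x == 1))
        } else {
          paste(table(x), collapse = "/")
        }
      }
      s1 <- fmt(x1)
      s0 <- fmt(x0)
    }
    data.frame(
      variable = v, group1 = s1, group0 = s0,
      p_value = res$p, test = res$method, stringsAsFactors = FALSE
    )
  })
  header <- data.frame(
    variable = "n", group1 = as.character(sum(g == 1)),
    group0 = as.character(sum(g == 0)), p_value = NA_real_,
    test = "", stringsAsFactors = FALSE
  )
  out <- rbind(header, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
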