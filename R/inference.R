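check_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must hold non-negative integer counts", call. = FALSE)
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  table
}

#' Chi-square test on a pooled contingency table
#'
#' Pearson chi-square with `(r-1)(c-1)` degrees of freedom; the Yates
#' continuity correction is applied if and only if the table is 2x2 (and
#' `correct = TRUE`). The corrected form is the package default because it
#' is what reproduces the study's published bivariate p-values.
#'
#' @param table count matrix (variable levels x periods).
#' @param correct apply the continuity correction on 2x2 tables.
#' @return a one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `correction`.
#' @export
#' @examples
#' chisq_period_test(matrix(c(12, 63, 19, 55), 2, 2))
chisq_period_test <- function(table, correct = TRUE) {
  table <- check_contingency(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square undefined: zero row or column margin", call. = FALSE)
  }
  is2x2 <- nrow(table) == 2 && ncol(table) == 2
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct && is2x2))
  tibble::tibble(method = "chi-square",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 correction = correct && is2x2)
}

#' Fisher exact test on a pooled contingency table
#'
#' Two-sided exact test with the probability-mass criterion: the p-value
#' sums the probabilities of all tables with the observed margins whose
#' hypergeometric probability does not exceed that of the observed table.
#' For tables too large for exact enumeration, a seeded Monte-Carlo mode is
#' available.
#'
#' @param table count matrix.
#' @param simulate use Monte-Carlo p-value estimation instead of full
#'   enumeration.
#' @param B number of Monte-Carlo tables.
#' @param seed seed for the Monte-Carlo mode.
#' @return a one-row tibble like [chisq_period_test()].
#' @export
fisher_period_test <- function(table, simulate = FALSE, B = 1e5, seed = 1L) {
  table <- check_contingency(table)
  ht <- if (simulate) {
    isolate_seed(seed, stats::fisher.test(table, simulate.p.value = TRUE, B = B))
  } else {
    tryCatch(stats::fisher.test(table),
             error = function(e) {
               stop("exact enumeration failed (", conditionMessage(e),
                    "); retry with simulate = TRUE for a seeded Monte-Carlo ",
                    "p-value", call. = FALSE)
             })
  }
  tibble::tibble(method = "fisher", statistic = NA_real_, df = NA_real_,
                 p_value = ht$p.value, correction = FALSE)
}

#' Choose between chi-square and Fisher for a table
#'
#' The study's selection rule: chi-square when every observed cell holds at
#' least 5 records, Fisher's exact test otherwise.
#'
#' @param table count matrix.
#' @return `"chi-square"` or `"fisher"`.
#' @export
select_test <- function(table) {
  table <- check_contingency(table)
  if (all(table >= 5)) "chi-square" else "fisher"
}

#' Test a variable-by-period table with the study's selection rule
#'
#' @inheritParams chisq_period_test
#' @param ... passed to [fisher_period_test()] when Fisher is selected.
#' @return a one-row tibble like [chisq_period_test()].
#' @export
period_test <- function(table, correct = TRUE, ...) {
  if (select_test(table) == "chi-square") {
    chisq_period_test(table, correct = correct)
  } else {
    fisher_period_test(table, ...)
  }
}

#' Pooled-variance two-sample t-test from group summaries
#'
#' Student's t test computed from sufficient statistics only (per-group n,
#' mean, SD), which is all a federation coordinator ever sees. Degrees of
#' freedom are `n1 + n2 - 2`; the p-value is two-sided. Zero pooled
#' variance with equal means gives `t = 0, p = 1`; with distinct means the
#' result is flagged degenerate.
#'
#' @param summaries a two-row data frame with columns `n`, `mean`, `sd`
#'   (one row per comparison group).
#' @return a one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
#' @examples
#' student_t(tibble::tibble(n = c(75, 74), mean = c(179.7, 255.2),
#'                          sd = c(267.1, 274.6)))
student_t <- function(summaries) {
  summaries <- tibble::as_tibble(summaries)
  stopifnot(nrow(summaries) == 2, all(c("n", "mean", "sd") %in% names(summaries)),
            all(summaries$n >= 2), all(summaries$sd >= 0))
  n1 <- summaries$n[1]; n2 <- summaries$n[2]
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * summaries$sd[1]^2 + (n2 - 1) * summaries$sd[2]^2) / df
  delta <- summaries$mean[1] - summaries$mean[2]
  if (sp2 == 0) {
    if (delta == 0) {
      return(tibble::tibble(method = "student-t", statistic = 0, df = df,
                            p_value = 1, degenerate = FALSE))
    }
    return(tibble::tibble(method = "student-t", statistic = sign(delta) * Inf,
                          df = df, p_value = 0, degenerate = TRUE))
  }
  tval <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(method = "student-t", statistic = tval, df = df,
                 p_value = 2 * stats::pt(-abs(tval), df), degenerate = FALSE)
}

#' Differentially private two-sample t test across the federation
#'
#' Each node releases, for each of the two comparison groups, a noisy count,
#' sum and sum of squares of the clamped variable - six Laplace releases at
#' `epsilon_total / 6` each, so the per-node charge is exactly
#' `epsilon_total`. The coordinator pools the noisy aggregates into group
#' summaries (noisy pooled counts rounded to the nearest integer and floored
#' at 2 before the degrees of freedom, as free post-processing) and applies
#' [student_t()]. In noise-free mode this reduces exactly to the plain
#' pooled t test.
#'
#' @param nodes named list of per-center cohort tibbles.
#' @param variable quantitative variable to compare.
#' @param group_var two-level grouping variable (default `"period"`).
#' @param epsilon_total total per-node privacy budget for the test.
#' @param stream a [dp_stream()].
#' @param ledger optional [new_ledger()].
#' @param config a [study_config()] (supplies clamp bounds from the schema).
#' @param bounds optional explicit clamp bounds overriding the schema.
#' @return a one-row tibble like [student_t()] with added `epsilon`.
#' @export
dp_t_test <- function(nodes, variable, group_var = "period",
                      epsilon_total = 60, stream, ledger = NULL,
                      config = study_config(), bounds = NULL) {
  stopifnot(epsilon_total > 0)
  if (is.null(bounds)) bounds <- schema_bounds(config$schema, variable)
  groups <- if (group_var == "period") c("before", "after") else {
    levels(factor(nodes[[1]][[group_var]]))
  }
  if (length(groups) != 2) stop("dp_t_test needs exactly two groups", call. = FALSE)
  eps <- epsilon_total / 6
  agg <- array(0, dim = c(2, 3), dimnames = list(groups, c("n", "sum", "sumsq")))
  for (id in names(nodes)) {
    df <- nodes[[id]]
    for (g in groups) {
      x <- df[[variable]][df[[group_var]] == g]
      x <- clamp(x[!is.na(x)], bounds)
      for (part in c("ttest.count", "ttest.sum", "ttest.sumsq")) {
        charge_ledger(ledger, id, paste0(part, ".", g), eps)
      }
      agg[g, "n"] <- agg[g, "n"] + laplace_release(length(x), eps, 1, stream)
      agg[g, "sum"] <- agg[g, "sum"] +
        laplace_release(sum(x), eps, max(abs(bounds)), stream)
      agg[g, "sumsq"] <- agg[g, "sumsq"] +
        laplace_release(sum(x^2), eps, max(bounds^2), stream)
    }
  }
  degenerate_n <- any(round(agg[, "n"]) < 2)
  n <- unname(pmax(round(agg[, "n"]), 2))
  m <- unname(agg[, "sum"]) / n
  v <- pmax((unname(agg[, "sumsq"]) - unname(agg[, "sum"])^2 / n) / (n - 1), 0)
  res <- student_t(tibble::tibble(n = n, mean = m, sd = sqrt(v)))
  res$degenerate <- res$degenerate | degenerate_n
  res$epsilon <- epsilon_total
  res
}

#' Screen bivariate p-values for confounders
#'
#' The study rule: a covariate enters the multivariate models when its
#' bivariate p-value is strictly below the threshold (default .20).
#'
#' @param p_values named numeric vector (or data frame with columns
#'   `variable`, `p_value`) of bivariate p-values per covariate.
#' @param threshold selection threshold in (0, 1).
#' @return character vector of selected covariate names.
#' @export
#' @examples
#' screen_confounders(c(organization = .99, gender = .79, age_class = .38,
#'                      bmi_class = .39, treatment_category = 1e-4,
#'                      creatinemia = .47))
screen_confounders <- function(p_values, threshold = 0.20) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.data.frame(p_values)) {
    p_values <- stats::setNames(p_values$p_value, p_values$variable)
  }
  names(p_values)[!is.na(p_values) & p_values < threshold]
}
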