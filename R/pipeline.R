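#' Flowchart accounting and analysis-set construction
#'
#' Reproduces the study's patient-accounting step. All included patients
#' enter the progression analysis (patients who transferred to another
#' center are censored at the transfer time); the duration analysis
#' additionally excludes the transferred patients entirely, since their
#' first-line duration is not fully observed at the enrolling center.
#'
#' @param nodes named list of per-center cohort tibbles.
#' @param config a [study_config()].
#' @return a list with `accounting` (per-period tibble: included,
#'   progressed, progression_free, transferred, duration_n),
#'   `progression_nodes` and `duration_nodes` (node lists with derived
#'   outcome columns).
#' @export
#' @examples
#' fc <- run_flowchart(as_nodes(build_fixture(seed = 1)))
#' fc$accounting
run_flowchart <- function(nodes, config = study_config()) {
  nodes <- lapply(nodes, derive_outcome, config = config)
  pooled <- dplyr::bind_rows(nodes)
  accounting <- pooled |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      included = dplyr::n(),
      progressed = sum(.data$event == "progressed"),
      progression_free = sum(.data$censor_reason == "end_of_window"),
      transferred = sum(.data$censor_reason == "transfer"),
      duration_n = sum(.data$censor_reason != "transfer"),
      .groups = "drop")
  duration_nodes <- lapply(nodes, function(df) {
    dplyr::filter(df, .data$censor_reason != "transfer")
  })
  if (sum(accounting$duration_n) == 0) {
    warning("all patients transferred: the duration analysis set is empty")
  }
  list(accounting = accounting, progression_nodes = nodes,
       duration_nodes = duration_nodes)
}

univariate_variables <- function() {
  list(quantitative = c("firstline_duration_days", "creatinemia"),
       categorical = c("gender", "age_class", "bmi_class",
                       "treatment_category"))
}

#' Federated univariate descriptives, with or without differential privacy
#'
#' Without DP the pooled mean, SD and the 5/25/50/75/95 percentile grid are
#' reported for quantitative variables (extrema are withheld as disclosive)
#' and pooled counts with percentages for categorical ones. With DP each
#' node instead releases noisy aggregates at `epsilon_univariate` per
#' statistic - count, mean, SD, median, minimum and maximum for
#' quantitative variables (minima and maxima become releasable once
#' noised), one noisy histogram per categorical variable - and the
#' coordinator pools the noisy pieces.
#'
#' @param nodes named list of per-center cohort tibbles.
#' @param config a [study_config()].
#' @param dp logical: add local DP noise.
#' @param stream a [dp_stream()] (required when `dp = TRUE`).
#' @param ledger optional [new_ledger()].
#' @return a tibble: `variable`, `statistic`, `value`, `epsilon` (NA for
#'   exact cells), `masked`.
#' @export
run_univariate <- function(nodes, config = study_config(), dp = FALSE,
                           stream = NULL, ledger = NULL) {
  vars <- univariate_variables()
  eps <- config$epsilon_univariate
  dpmode <- if (dp) "local" else "none"
  rows <- list()
  add <- function(variable, statistic, value, epsilon = NA_real_, masked = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      variable = variable, statistic = statistic, value = value,
      epsilon = epsilon, masked = masked)
  }
  safe_query <- function(...) {
    tryCatch(run_query(...), error = function(e) NULL)
  }
  for (v in vars$quantitative) {
    qn <- safe_query(nodes, v, "count", dp = dpmode, epsilon = eps,
                     stream = stream, ledger = ledger, config = config)
    if (is.null(qn)) { add(v, "n", NA_real_, masked = TRUE); next }
    add(v, "n", qn$value, if (dp) eps else NA_real_)
    add(v, "mean",
        run_query(nodes, v, "mean", dp = dpmode, epsilon = eps,
                  stream = stream, ledger = ledger, config = config)$value,
        if (dp) eps else NA_real_)
    add(v, "sd",
        run_query(nodes, v, "sd", dp = dpmode, epsilon = eps,
                  stream = stream, ledger = ledger, config = config)$value,
        if (dp) eps else NA_real_)
    if (dp) {
      add(v, "median",
          run_query(nodes, v, "quantile", q = 0.5, dp = "local", epsilon = eps,
                    stream = stream, ledger = ledger, config = config)$value, eps)
      add(v, "min",
          run_query(nodes, v, "min", dp = "local", epsilon = eps,
                    stream = stream, ledger = ledger, config = config)$value, eps)
      add(v, "max",
          run_query(nodes, v, "max", dp = "local", epsilon = eps,
                    stream = stream, ledger = ledger, config = config)$value, eps)
    } else {
      qq <- run_query(nodes, v, "percentiles", config = config)$value
      for (nmq in names(qq)) add(v, nmq, qq[[nmq]])
      add(v, "median", unname(qq[["p50"]]))
    }
  }
  for (v in vars$categorical) {
    res <- safe_query(nodes, v, "histogram", dp = dpmode, epsilon = eps,
                      stream = stream, ledger = ledger, config = config)
    if (is.null(res)) { add(v, "count", NA_real_, masked = TRUE); next }
    cells <- res$value
    total <- sum(cells)
    for (lv in names(cells)) {
      add(v, paste0("count.", lv), as.numeric(cells[[lv]]),
          if (dp) eps else NA_real_)
      add(v, paste0("pct.", lv),
          if (total > 0) 100 * cells[[lv]] / total else NA_real_,
          if (dp) eps else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

bivariate_variables <- function() {
  list(interest_categorical = "progression",
       interest_quantitative = "firstline_duration_days",
       covariable_categorical = c("organization", "gender", "age_class",
                                  "bmi_class", "treatment_category"),
       covariable_quantitative = "creatinemia")
}

period_table_query <- function(nodes, variable, config, dp, eps, stream, ledger) {
  res <- run_query(nodes, variable, "histogram", by = "period",
                   dp = if (dp) "local" else "none", epsilon = eps,
                   stream = stream, ledger = ledger, config = config)
  res$value
}

progression_period_table <- function(nodes, config, dp, eps, stream, ledger) {
  # progression status is a derived two-level categorical: No / Yes
  nodes2 <- lapply(nodes, function(df) {
    df$progression <- factor(ifelse(df$event == "progressed", "Yes", "No"),
                             levels = c("No", "Yes"))
    df
  })
  res <- run_query(nodes2, "progression", "histogram", by = "period",
                   dp = if (dp) "local" else "none", epsilon = eps,
                   stream = stream, ledger = ledger, config = config)
  res$value
}

#' Federated bivariate screening, with or without differential privacy
#'
#' Builds a variable-by-period contingency table for every categorical
#' variable (pooled across nodes; noisy per-node tables at
#' `epsilon_univariate` when `dp = TRUE`), applies the study's test
#' selection rule (chi-square when all cells >= 5, Fisher otherwise), and
#' runs the (DP) two-sample t test for quantitative covariates. Center
#' membership ("organization") is public federation metadata, so its table
#' is never noised.
#'
#' @param nodes node list *with outcome columns* (see [run_flowchart()]).
#' @param config a [study_config()].
#' @param dp logical; noise the tables and use the DP t test.
#' @param stream,ledger as in [run_univariate()].
#' @param correct apply the Yates correction on 2x2 tables.
#' @return a list: `table` (tibble of per-variable tests) and `p_values`
#'   (named vector over covariates, ready for [screen_confounders()]).
#' @export
run_bivariate <- function(nodes, config = study_config(), dp = FALSE,
                          stream = NULL, ledger = NULL, correct = TRUE) {
  eps <- config$epsilon_univariate
  rows <- list()
  pvals <- c()
  add <- function(variable, role, method, p_value, epsilon = NA_real_,
                  degenerate = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      variable = variable, role = role, method = method, p_value = p_value,
      epsilon = epsilon, degenerate = degenerate)
  }
  test_table <- function(tab) {
    tryCatch(period_test(tab, correct = correct),
             error = function(e) fisher_period_test(tab))
  }
  # a fully masked or failed variable degrades to an NA p-value; the run
  # continues and the variable can never be selected as a confounder
  masked_row <- function(variable, role) {
    add(variable, role, "masked", NA_real_, NA_real_, TRUE)
  }
  # variable of interest: progression
  tryCatch({
    ptab <- progression_period_table(nodes, config, dp, eps, stream, ledger)
    tt <- test_table(ptab)
    add("progression", "interest", tt$method, tt$p_value,
        if (dp) eps else NA_real_)
  }, error = function(e) masked_row("progression", "interest"))
  # variable of interest: first-line duration (t test)
  tryCatch({
    tdur <- bivariate_t(nodes, "firstline_duration_days", config, dp, stream, ledger)
    add("firstline_duration_days", "interest", tdur$method, tdur$p_value,
        if (dp) config$epsilon_ttest else NA_real_, tdur$degenerate)
  }, error = function(e) masked_row("firstline_duration_days", "interest"))
  # organization: center-by-period counts, public metadata, never noised
  org <- sapply(names(nodes), function(id) {
    c(before = sum(nodes[[id]]$period == "before"),
      after = sum(nodes[[id]]$period == "after"))
  })
  org_tab <- t(org)
  tt <- test_table(org_tab)
  add("organization", "covariable", tt$method, tt$p_value)
  pvals["organization"] <- tt$p_value
  for (v in c("gender", "age_class", "bmi_class", "treatment_category")) {
    tryCatch({
      tab <- period_table_query(nodes, v, config, dp, eps, stream, ledger)
      tt <- test_table(tab)
      add(v, "covariable", tt$method, tt$p_value, if (dp) eps else NA_real_)
      pvals[v] <- tt$p_value
    }, error = function(e) {
      masked_row(v, "covariable")
      pvals[v] <<- NA_real_
    })
  }
  tryCatch({
    tcr <- bivariate_t(nodes, "creatinemia", config, dp, stream, ledger)
    add("creatinemia", "covariable", tcr$method, tcr$p_value,
        if (dp) config$epsilon_ttest else NA_real_, tcr$degenerate)
    pvals["creatinemia"] <- tcr$p_value
  }, error = function(e) {
    masked_row("creatinemia", "covariable")
    pvals["creatinemia"] <<- NA_real_
  })
  list(table = dplyr::bind_rows(rows), p_values = pvals)
}

bivariate_t <- function(nodes, variable, config, dp, stream, ledger) {
  if (dp) {
    return(dp_t_test(nodes, variable, "period", config$epsilon_ttest,
                     stream = stream, ledger = ledger, config = config))
  }
  summ <- lapply(c("before", "after"), function(p) {
    vals <- unlist(lapply(nodes, function(df) {
      x <- df[[variable]][df$period == p]
      x[!is.na(x)]
    }))
    per_node <- dplyr::bind_rows(lapply(nodes, function(df) {
      x <- df[[variable]][df$period == p]
      x <- x[!is.na(x)]
      tibble::tibble(n = length(x), mean = mean(x), sd = stats::sd(x))
    }))
    per_node <- per_node[per_node$n >= 2, , drop = FALSE]
    tibble::tibble(n = sum(per_node$n), mean = pool_mean(per_node),
                   sd = pool_sd(per_node))
  })
  res <- student_t(dplyr::bind_rows(summ))
  res
}

#' Run the complete federated study
#'
#' Orchestrates the whole pipeline on a node set: flowchart accounting,
#' univariate descriptives (plain, plus a DP pass when `dp = TRUE`),
#' bivariate screening, confounder selection at the configured threshold,
#' then the two multivariate models on their respective analysis sets -
#' federated linear regression of first-line duration on period (plus
#' selected confounders) on the duration set, and the center-stratified
#' federated Cox model of progression on the progression set - finishing
#' with the CI-based significance calls and a ledger snapshot.
#'
#' @param nodes named list of per-center cohort tibbles.
#' @param config a [study_config()].
#' @param dp also run the DP pass (univariate + bivariate + DP t tests).
#' @param seed root seed for all DP noise (required when `dp = TRUE`).
#' @param noise_free test-only switch propagated to [dp_stream()].
#' @param correct Yates correction for 2x2 tables.
#' @return an `analysis_report` list; see [write_report()].
#' @export
#' @examples
#' rep <- run_full_study(as_nodes(build_fixture(seed = 1)))
#' rep$confounders
run_full_study <- function(nodes, config = study_config(), dp = FALSE,
                           seed = NULL, noise_free = FALSE, correct = TRUE) {
  if (dp && is.null(seed)) stop("a seed is required when dp = TRUE", call. = FALSE)
  stream <- if (dp) dp_stream(seed, noise_free = noise_free)
  ledger <- new_ledger()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  fc <- stage("flowchart", run_flowchart(nodes, config))
  uni <- stage("univariate",
               run_univariate(fc$progression_nodes, config, dp = FALSE))
  uni_dp <- if (dp) {
    stage("univariate-dp",
          run_univariate(fc$progression_nodes, config, dp = TRUE,
                         stream = stream, ledger = ledger))
  }
  biv <- stage("bivariate",
               run_bivariate(fc$progression_nodes, config, dp = FALSE,
                             correct = correct))
  biv_dp <- if (dp) {
    stage("bivariate-dp",
          run_bivariate(fc$progression_nodes, config, dp = TRUE,
                        stream = stream, ledger = ledger, correct = correct))
  }
  p_for_screening <- if (dp) biv_dp$p_values else biv$p_values
  confounders <- stage("screening",
                       screen_confounders(p_for_screening,
                                          config$screening_alpha))
  model_terms <- setdiff(confounders, "organization")
  ols_formula <- stats::reformulate(c("period", model_terms),
                                    response = "firstline_duration_days")
  cox_formula <- stats::reformulate(c("period", model_terms))
  ols <- stage("linear-regression", fed_ols(fc$duration_nodes, ols_formula))
  cox <- stage("cox-model", fed_cox(fc$progression_nodes, cox_formula, config))
  structure(list(
    flowchart = fc$accounting,
    univariate = uni,
    univariate_dp = uni_dp,
    bivariate = biv$table,
    bivariate_dp = if (dp) biv_dp$table,
    p_values = biv$p_values,
    p_values_dp = if (dp) biv_dp$p_values,
    confounders = confounders,
    ols = ols, cox = cox,
    significance = list(ols = significance_by_ci(ols),
                        cox = significance_by_ci(cox)),
    ledger = ledger_entries(ledger),
    meta = list(dp = dp, seed = seed, noise_free = noise_free,
                correct = correct, n_nodes = length(nodes),
                screening_alpha = config$screening_alpha)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", if (x$meta$dp) "with DP pass" else "plain", "\n")
  cat("\nFlowchart:\n"); print(x$flowchart)
  cat("\nBivariate p-values:\n"); print(round(x$p_values, 4))
  cat("\nSelected confounders:", paste(x$confounders, collapse = ", "), "\n")
  cat("\nLinear regression (duration ~ period",
      if (length(setdiff(x$confounders, "organization"))) "+ confounders", "):\n")
  print(tidy(x$ols))
  cat("\nCox model (progression, stratified by center), hazard ratios:\n")
  print(tidy(x$cox, exponentiate = TRUE))
  invisible(x)
}

format_p <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.2f", p)))
}

#' Write an analysis report to disk
#'
#' Emits the machine-readable JSON report and a human-readable Markdown
#' rendering (p-values shown to 2 decimals, `<.001` below 0.001; full
#' precision retained in the JSON). Deterministic: identical inputs and
#' seed give byte-identical files.
#'
#' @param report an `analysis_report` from [run_full_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  to_json <- report
  to_json$ols <- list(coefficients = tidy(report$ols), glance = glance(report$ols))
  to_json$cox <- list(coefficients = tidy(report$cox, exponentiate = TRUE),
                      glance = glance(report$cox))
  jsonlite::write_json(to_json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  lines <- c(
    "# Federated study report",
    "",
    "## Flowchart",
    "",
    knit_table(report$flowchart),
    "",
    "## Bivariate screening",
    "",
    knit_table(dplyr::mutate(report$bivariate, p_value = format_p(.data$p_value))),
    "",
    sprintf("Selected confounders (p < %.2g): %s",
            report$meta$screening_alpha %||% 0.2,
            if (length(report$confounders)) paste(report$confounders, collapse = ", ")
            else "(none)"),
    "",
    "## Linear regression (first-line duration)",
    "",
    knit_table(tidy(report$ols)),
    "",
    "## Cox model (progression, hazard-ratio scale)",
    "",
    knit_table(tidy(report$cox, exponentiate = TRUE)),
    "")
  if (!is.null(report$bivariate_dp)) {
    lines <- c(lines,
               "## Bivariate screening with differential privacy",
               "",
               knit_table(dplyr::mutate(report$bivariate_dp,
                                        p_value = format_p(.data$p_value))),
               "",
               sprintf("Total privacy budget spent: %s",
                       format(sum(report$ledger$epsilon))),
               "")
  }
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}

# minimal fixed-format markdown table renderer
knit_table <- function(df) {
  df <- as.data.frame(df)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 6, trim = TRUE) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Plot the bivariate screening p-values
#'
#' @param report an `analysis_report`.
#' @return a ggplot bar chart of -log10 p per variable with the screening
#'   threshold drawn.
#' @export
plot_screening <- function(report) {
  tb <- report$bivariate
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$variable, .data$p_value),
                                   y = -log10(pmax(.data$p_value, 1e-6)))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.20), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 p",
                  title = "Bivariate screening (dashed: p = .20)") +
    ggplot2::theme_minimal()
}
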