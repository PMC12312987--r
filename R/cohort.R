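#' Variable schema for the harmonized cohort table
#'
#' Every node in the federation ingests patient-level data through the same
#' flat schema. Each variable declares its kind and, for quantitative
#' variables, the clamping bounds `[clamp_lower, clamp_upper]` that every
#' differentially private release of that variable uses to bound
#' per-individual sensitivity. The bounds are public study parameters, not
#' data-derived quantities, and can be overridden per study.
#'
#' @param creatinemia_bounds length-2 numeric, clamp bounds for blood
#'   creatinine in µmol/L.
#' @param duration_bounds length-2 numeric, clamp bounds for first-line
#'   treatment duration in days.
#'
#' @return A tibble with one row per variable: `name`, `kind`
#'   (`"categorical"`, `"quantitative"`, `"date"` or `"duration"`),
#'   `categories` (list-column of ordered level sets), `clamp_lower`,
#'   `clamp_upper`, `units`.
#' @export
#' @examples
#' cohort_schema()
cohort_schema <- function(creatinemia_bounds = c(20, 300),
                          duration_bounds = c(0, 1500)) {
  stopifnot(length(creatinemia_bounds) == 2, creatinemia_bounds[1] < creatinemia_bounds[2],
            length(duration_bounds) == 2, duration_bounds[1] < duration_bounds[2])
  sch <- tibble::tibble(
    name = c("patient_id", "center", "inclusion_date", "gender", "age_class",
             "bmi_class", "treatment_category", "creatinemia",
             "firstline_duration_days", "secondline_start_day", "death_day",
             "transfer_day"),
    kind = c("id", "categorical", "date", "categorical", "categorical",
             "categorical", "categorical", "quantitative",
             "quantitative", "duration", "duration", "duration"),
    categories = list(
      NULL, NULL, NULL,
      c("Female", "Male"),
      c("<55", "55-65", ">65"),
      c("<18.5", "18.5-25", ">25"),
      c("Chemotherapy", "Chemotherapy+angiogenesis inhibitor",
        "Chemotherapy+immunotherapy", "Immunotherapy"),
      NULL, NULL, NULL, NULL, NULL),
    clamp_lower = c(NA, NA, NA, NA, NA, NA, NA, creatinemia_bounds[1],
                    duration_bounds[1], NA, NA, NA),
    clamp_upper = c(NA, NA, NA, NA, NA, NA, NA, creatinemia_bounds[2],
                    duration_bounds[2], NA, NA, NA),
    units = c("", "", "ISO-8601 date", "", "years", "kg/m2", "",
              "umol/L", "days", "days", "days", "days")
  )
  validate_schema(sch)
  sch
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("name", "kind", "categories", "clamp_lower", "clamp_upper") %in%
                  names(schema)))
  if (anyDuplicated(schema$name)) {
    stop("schema variable names must be unique", call. = FALSE)
  }
  cat_rows <- schema$kind == "categorical" & schema$name != "center"
  n_lev <- vapply(schema$categories[cat_rows], length, integer(1))
  if (any(n_lev < 2)) {
    stop("categorical schema variables need at least 2 categories", call. = FALSE)
  }
  quant <- schema$kind == "quantitative"
  if (any(schema$clamp_lower[quant] >= schema$clamp_upper[quant])) {
    stop("quantitative clamp bounds must satisfy lower < upper", call. = FALSE)
  }
  invisible(schema)
}

#' Bounds declared by the schema for one variable
#'
#' @param schema a schema tibble from [cohort_schema()].
#' @param variable variable name.
#' @return length-2 numeric `c(lower, upper)`.
#' @export
schema_bounds <- function(schema, variable) {
  row <- schema[schema$name == variable, ]
  if (nrow(row) != 1) stop("unknown variable: ", variable, call. = FALSE)
  if (!is.na(row$clamp_lower) && !is.na(row$clamp_upper)) {
    return(c(row$clamp_lower, row$clamp_upper))
  }
  stop("no clamp bounds declared for variable: ", variable, call. = FALSE)
}

#' Study configuration
#'
#' Bundles the calendar windows that define the two inclusion periods, the
#' follow-up window, the disclosure threshold and the privacy budgets used by
#' the pipeline. The defaults are the study's own settings: the period
#' "before" runs from 2019-03-01 to 2020-03-01 and "after" from 2020-03-02 to
#' 2021-03-31 (both closed), follow-up is 24 months, and the privacy budgets
#' are epsilon = 5.0 for each univariate release and epsilon = 60.0 for the
#' differentially private t test.
#'
#' @param before_window,after_window length-2 Date vectors (closed intervals).
#' @param observation_days administrative censoring horizon in days.
#' @param disclosure_min_cell minimum cell count a node will release.
#' @param epsilon_univariate privacy budget per univariate DP release.
#' @param epsilon_ttest total privacy budget per node for the DP t test.
#' @param screening_alpha bivariate p-value threshold for confounder
#'   screening (strict: p < alpha selects).
#' @param schema variable schema, see [cohort_schema()].
#'
#' @return an object of class `study_config`.
#' @export
study_config <- function(before_window = as.Date(c("2019-03-01", "2020-03-01")),
                         after_window = as.Date(c("2020-03-02", "2021-03-31")),
                         observation_days = 730L,
                         disclosure_min_cell = 3L,
                         epsilon_univariate = 5.0,
                         epsilon_ttest = 60.0,
                         screening_alpha = 0.20,
                         schema = cohort_schema()) {
  before_window <- as.Date(before_window)
  after_window <- as.Date(after_window)
  stopifnot(length(before_window) == 2, length(after_window) == 2,
            before_window[1] <= before_window[2],
            after_window[1] <= after_window[2],
            observation_days > 0,
            disclosure_min_cell >= 1,
            epsilon_univariate > 0, epsilon_ttest > 0,
            screening_alpha > 0, screening_alpha < 1)
  if (before_window[2] >= after_window[1] && after_window[2] >= before_window[1]) {
    # overlap test for closed intervals
    if (max(before_window[1], after_window[1]) <= min(before_window[2], after_window[2])) {
      stop("period windows must be disjoint", call. = FALSE)
    }
  }
  structure(
    list(before_window = before_window, after_window = after_window,
         observation_days = as.integer(observation_days),
         disclosure_min_cell = as.integer(disclosure_min_cell),
         epsilon_univariate = epsilon_univariate,
         epsilon_ttest = epsilon_ttest,
         screening_alpha = screening_alpha,
         schema = schema),
    class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  before: ", format(x$before_window[1]), " .. ", format(x$before_window[2]), "\n", sep = "")
  cat("  after:  ", format(x$after_window[1]), " .. ", format(x$after_window[2]), "\n", sep = "")
  cat("  observation_days:", x$observation_days,
      " disclosure_min_cell:", x$disclosure_min_cell, "\n")
  cat("  epsilon_univariate:", x$epsilon_univariate,
      " epsilon_ttest:", x$epsilon_ttest,
      " screening_alpha:", x$screening_alpha, "\n")
  invisible(x)
}

#' Assign each inclusion date to a study period
#'
#' Both windows are closed calendar intervals; a date falling in neither is an
#' error rather than a silent guess, because every in-study patient must
#' belong to exactly one period.
#'
#' @param dates Date vector.
#' @param config a [study_config()].
#' @return character vector of `"before"` / `"after"`.
#' @export
#' @examples
#' assign_period(as.Date(c("2019-06-15", "2020-03-02")), study_config())
assign_period <- function(dates, config = study_config()) {
  dates <- as.Date(dates)
  before <- dates >= config$before_window[1] & dates <= config$before_window[2]
  after <- dates >= config$after_window[1] & dates <= config$after_window[2]
  bad <- !(before | after) | is.na(dates)
  if (any(bad)) {
    stop("inclusion date(s) outside both study windows: ",
         paste(format(dates[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(before, "before", "after")
}

cohort_columns <- function() {
  c("patient_id", "center", "inclusion_date", "gender", "age_class",
    "bmi_class", "treatment_category", "creatinemia",
    "firstline_duration_days", "secondline_start_day", "death_day",
    "transfer_day")
}

#' Validate a cohort table against the schema
#'
#' Checks the contract every node enforces at ingestion: known categorical
#' levels, unique patient pseudonyms within the node set, non-negative day
#' offsets and parseable dates. Missing quantitative values are allowed and
#' preserved.
#'
#' @param data a data frame of patient records.
#' @param config a [study_config()] (supplies the schema and windows).
#' @return the validated tibble (invisibly classed `cohort_table`), with a
#'   `period` column derived from `inclusion_date`.
#' @export
validate_cohort <- function(data, config = study_config()) {
  schema <- config$schema
  need <- cohort_columns()
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[, need]
  data$inclusion_date <- as.Date(data$inclusion_date)
  if (anyNA(data$inclusion_date)) {
    stop("malformed inclusion_date in row(s) ",
         paste(which(is.na(data$inclusion_date)), collapse = ", "), call. = FALSE)
  }
  dup <- data |>
    dplyr::count(.data$center, .data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate patient_id within a node: ",
         paste(dup$patient_id, collapse = ", "), call. = FALSE)
  }
  for (v in c("gender", "age_class", "bmi_class", "treatment_category")) {
    levels_v <- schema$categories[[which(schema$name == v)]]
    vals <- data[[v]]
    bad <- !is.na(vals) & !(vals %in% levels_v)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("unknown category for %s in row %d: \"%s\"", v, i, vals[i]),
           call. = FALSE)
    }
    data[[v]] <- factor(vals, levels = levels_v)
  }
  for (v in c("creatinemia", "firstline_duration_days", "secondline_start_day",
              "death_day", "transfer_day")) {
    data[[v]] <- as.numeric(data[[v]])
    if (any(data[[v]] < 0, na.rm = TRUE)) {
      stop("negative day offset / value in column ", v, call. = FALSE)
    }
  }
  data$period <- if (nrow(data) > 0) {
    factor(assign_period(data$inclusion_date, config),
           levels = c("before", "after"))
  } else {
    factor(character(), levels = c("before", "after"))
  }
  class(data) <- c("cohort_table", class(data))
  data
}

#' Read one node's cohort CSV
#'
#' The CSV dialect is UTF-8 with a header row whose names are exactly the
#' schema variable names; dates are ISO-8601; blank cells are missing values.
#'
#' @param path CSV file path.
#' @param config a [study_config()].
#' @return a validated `cohort_table` tibble with a derived `period` column.
#' @export
read_cohort <- function(path, config = study_config()) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    center = readr::col_character(),
    inclusion_date = readr::col_date(format = ""),
    gender = readr::col_character(),
    age_class = readr::col_character(),
    bmi_class = readr::col_character(),
    treatment_category = readr::col_character(),
    creatinemia = readr::col_double(),
    firstline_duration_days = readr::col_double(),
    secondline_start_day = readr::col_double(),
    death_day = readr::col_double(),
    transfer_day = readr::col_double()))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed cohort CSV (row ", prob$row[1], "): ", prob$expected[1],
         call. = FALSE)
  }
  validate_cohort(raw, config)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writing then reading reproduces the table
#' record for record.
#'
#' @param cohort a cohort tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- tibble::as_tibble(cohort)[, cohort_columns()]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Derive the progression outcome for every patient
#'
#' Disease progression at 24 months is proxied by the start of a second
#' treatment line or death, whichever comes first. A patient whose proxy
#' falls after their censoring horizon - the earlier of the administrative
#' window end and a transfer to another center - is censored at that horizon
#' with the matching reason.
#'
#' @param cohort a validated cohort tibble.
#' @param config a [study_config()].
#' @return the cohort with three added columns: `time_days`, `event`
#'   (`"progressed"` / `"censored"`) and `censor_reason`
#'   (`"none"` / `"end_of_window"` / `"transfer"`).
#' @export
#' @examples
#' fx <- build_fixture(seed = 1)
#' dplyr::count(derive_outcome(fx), event, censor_reason)
derive_outcome <- function(cohort, config = study_config()) {
  for (v in c("secondline_start_day", "death_day", "transfer_day")) {
    if (any(cohort[[v]] < 0, na.rm = TRUE)) {
      stop("negative day offset in ", v, call. = FALSE)
    }
  }
  horizon <- pmin(config$observation_days,
                  dplyr::coalesce(cohort$transfer_day, Inf))
  proxy <- pmin(dplyr::coalesce(cohort$secondline_start_day, Inf),
                dplyr::coalesce(cohort$death_day, Inf))
  progressed <- proxy <= horizon
  cohort$time_days <- ifelse(progressed, proxy, horizon)
  cohort$event <- ifelse(progressed, "progressed", "censored")
  cohort$censor_reason <- dplyr::case_when(
    progressed ~ "none",
    horizon == config$observation_days ~ "end_of_window",
    .default = "transfer")
  cohort
}

#' Read or write a study configuration file
#'
#' The study configuration (period windows, follow-up horizon, disclosure
#' threshold, privacy budgets and per-variable clamp bounds) lives in a
#' single YAML file with nested sections, so a whole run is reproducible from
#' one text artifact.
#'
#' @param path YAML file path.
#' @return for `read_study_config`, a [study_config()]; for
#'   `write_study_config`, `path` invisibly.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  sch <- cohort_schema(
    creatinemia_bounds = unlist(y$clamp$creatinemia %||% c(20, 300)),
    duration_bounds = unlist(y$clamp$firstline_duration_days %||% c(0, 1500)))
  study_config(
    before_window = as.Date(unlist(y$periods$before)),
    after_window = as.Date(unlist(y$periods$after)),
    observation_days = y$observation_days %||% 730L,
    disclosure_min_cell = y$disclosure$min_cell_count %||% 3L,
    epsilon_univariate = y$privacy$epsilon_univariate %||% 5.0,
    epsilon_ttest = y$privacy$epsilon_ttest %||% 60.0,
    screening_alpha = y$screening_alpha %||% 0.20,
    schema = sch)
}

#' @rdname read_study_config
#' @param config a [study_config()] to serialize.
#' @export
write_study_config <- function(config, path) {
  y <- list(
    periods = list(before = as.character(config$before_window),
                   after = as.character(config$after_window)),
    observation_days = config$observation_days,
    disclosure = list(min_cell_count = config$disclosure_min_cell),
    privacy = list(epsilon_univariate = config$epsilon_univariate,
                   epsilon_ttest = config$epsilon_ttest),
    screening_alpha = config$screening_alpha,
    clamp = list(
      creatinemia = as.numeric(schema_bounds(config$schema, "creatinemia")),
      firstline_duration_days =
        as.numeric(schema_bounds(config$schema, "firstline_duration_days"))))
  yaml::write_yaml(y, path)
  invisible(path)
}
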