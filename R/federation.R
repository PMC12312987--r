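#' Disclosure-control policy for node releases
#'
#' Before a node releases any aggregate, it applies the minimum-cell-count
#' rule: a histogram bin or filtered subset size strictly below the
#' threshold masks the whole release. The pass is inclusive (a count equal
#' to the threshold is released), matching the default behaviour of
#' federated-analysis disclosure checks.
#'
#' @param min_cell_count minimum count any histogram cell must reach.
#' @param min_subset_n minimum size of any filtered subset.
#' @return a `disclosure_policy` list.
#' @export
disclosure_policy <- function(min_cell_count = 3L, min_subset_n = 3L) {
  stopifnot(min_cell_count >= 1, min_subset_n >= 1)
  structure(list(min_cell_count = as.integer(min_cell_count),
                 min_subset_n = as.integer(min_subset_n)),
            class = "disclosure_policy")
}

#' Apply the disclosure check to a local result
#'
#' A filtered subset whose size is below `min_subset_n` is masked. For
#' count tables, a cell with a small *nonzero* count (below
#' `min_cell_count`) is disclosive and masks the release; empty cells are
#' allowed, since revealing that a category is absent does not single out
#' any individual - this is the standard behaviour of federated-analysis
#' cell-count checks.
#'
#' @param local_result either a single subset size or a vector/matrix of
#'   cell counts computed on one node.
#' @param policy a [disclosure_policy()].
#' @param is_cells `TRUE` if `local_result` holds histogram cells, `FALSE`
#'   for a subset size.
#' @return `"ok"` or `"masked"`.
#' @export
#' @examples
#' check_disclosure(c(2, 40), disclosure_policy())  # masked
#' check_disclosure(c(3, 40), disclosure_policy())  # ok
check_disclosure <- function(local_result, policy = disclosure_policy(),
                             is_cells = length(local_result) > 1) {
  if (is_cells) {
    bad <- local_result > 0 & local_result < policy$min_cell_count
    if (any(bad)) "masked" else "ok"
  } else {
    if (any(local_result < policy$min_subset_n)) "masked" else "ok"
  }
}

# The only object a node ever emits. Payload entries are sufficient
# statistics (scalars, short vectors, small matrices); the constructor
# structurally refuses anything long enough to smuggle per-record data.
aggregate_message <- function(node, n, statistic, payload = NULL,
                              epsilon = NA_real_, status = c("ok", "masked")) {
  status <- match.arg(status)
  if (status == "masked") payload <- NULL
  if (!is.null(payload)) {
    stopifnot(is.list(payload), !is.null(names(payload)))
    for (el in payload) {
      if (!is.numeric(el)) {
        stop("message payload entries must be numeric", call. = FALSE)
      }
      lim <- if (is.matrix(el)) 32L * 32L else 32L
      if (length(el) > lim) {
        stop("message payload entry exceeds the aggregate-size limit; ",
             "per-record arrays cannot leave a node", call. = FALSE)
      }
    }
  }
  structure(list(node = node, n = n, statistic = statistic, payload = payload,
                 epsilon = epsilon, status = status),
            class = "aggregate_message")
}

#' @export
print.aggregate_message <- function(x, ...) {
  cat(sprintf("<aggregate_message> node=%s statistic=%s n=%s status=%s epsilon=%s\n",
              x$node, x$statistic, x$n, x$status, format(x$epsilon)))
  invisible(x)
}

#' Pool per-node means
#'
#' The coordinator's n-weighted combination of node-level means:
#' `sum(n_i * mean_i) / sum(n_i)`.
#'
#' @param messages a data frame with columns `n` and `mean` (one row per
#'   contributing node).
#' @return the pooled mean.
#' @export
#' @examples
#' pool_mean(tibble::tibble(n = c(75, 74), mean = c(179.7, 255.2)))
pool_mean <- function(messages) {
  messages <- tibble::as_tibble(messages)
  stopifnot(all(c("n", "mean") %in% names(messages)))
  if (nrow(messages) == 0 || sum(messages$n) <= 0) {
    stop("pool_mean: no contributing observations", call. = FALSE)
  }
  sum(messages$n * messages$mean) / sum(messages$n)
}

#' Pool per-node standard deviations
#'
#' Combines within-node and between-node variability:
#' `[sum((n_i - 1) s_i^2) + sum(n_i (m_i - m)^2)] / (N - 1)` with `m` the
#' pooled mean; equals the standard deviation of the concatenated raw data.
#'
#' @param messages a data frame with columns `n`, `mean`, `sd`.
#' @return the pooled standard deviation.
#' @export
pool_sd <- function(messages) {
  messages <- tibble::as_tibble(messages)
  stopifnot(all(c("n", "mean", "sd") %in% names(messages)))
  N <- sum(messages$n)
  if (N < 2) stop("pool_sd: need a total of at least 2 observations", call. = FALSE)
  m <- pool_mean(messages)
  v <- (sum((messages$n - 1) * messages$sd^2) +
          sum(messages$n * (messages$mean - m)^2)) / (N - 1)
  sqrt(max(v, 0))
}

#' Sum per-node contingency tables
#'
#' @param tables list of identically shaped named count vectors or matrices
#'   (same category sets in the same order).
#' @return their element-wise sum.
#' @export
pool_table <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  for (tb in tables[-1]) {
    same <- identical(dimnames(tb), dimnames(ref)) &&
      identical(dim(tb), dim(ref)) &&
      identical(names(tb), names(ref))
    if (!same) stop("pool_table: category sets differ across nodes", call. = FALSE)
  }
  Reduce(`+`, tables)
}

#' Pool per-node quantile vectors
#'
#' n-weighted average of the per-node quantiles on a common grid. This is an
#' approximation to the quantiles of the pooled data (exact pooling would
#' require exchanging order statistics across nodes, which the disclosure
#' model forbids); it is exact when node distributions coincide.
#'
#' @param quantiles list of named per-node quantile vectors (identical
#'   grids).
#' @param n numeric vector of node sizes, same length as `quantiles`.
#' @return the pooled quantile vector.
#' @export
pool_quantiles <- function(quantiles, n) {
  stopifnot(length(quantiles) == length(n), length(n) >= 1, sum(n) > 0)
  grid <- names(quantiles[[1]])
  for (qv in quantiles) {
    if (!identical(names(qv), grid)) {
      stop("pool_quantiles: quantile grids differ across nodes", call. = FALSE)
    }
  }
  mat <- do.call(rbind, quantiles)
  stats::setNames(as.numeric(crossprod(n, mat) / sum(n)), grid)
}

filter_nodes <- function(nodes, filter_quo) {
  if (rlang::quo_is_null(filter_quo)) return(nodes)
  lapply(nodes, function(df) dplyr::filter(df, !!filter_quo))
}

#' Run one federated statistical query
#'
#' Sends a query to every node; each node filters its local table, applies
#' the disclosure check, and answers with an [aggregate_message] of
#' sufficient statistics - exact (`dp = "none"`), noised locally before
#' leaving the node (`dp = "local"`, one ledger charge per node), or exact
#' with a single noise draw added by the coordinator after pooling
#' (`dp = "central"`, one ledger charge). Masked nodes are excluded from
#' pooling and flagged (or fail the query when `strict = TRUE`).
#'
#' @param nodes named list of per-center cohort tibbles (see [as_nodes()]).
#' @param variable variable to query.
#' @param statistic one of `"count"`, `"sum"`, `"mean"`, `"sd"`, `"min"`,
#'   `"max"`, `"quantile"`, `"percentiles"`, `"histogram"`.
#' @param filter optional row filter, as an unquoted expression on the
#'   cohort columns (e.g. `period == "before"`).
#' @param by optional second categorical variable; with
#'   `statistic = "histogram"` produces a variable-by-`by` contingency
#'   table per node.
#' @param dp `"none"`, `"local"` or `"central"`.
#' @param epsilon privacy budget (required when `dp != "none"`).
#' @param q quantile probability for `statistic = "quantile"`.
#' @param policy a [disclosure_policy()].
#' @param stream a [dp_stream()] (required when `dp != "none"`).
#' @param ledger optional [new_ledger()].
#' @param config a [study_config()] (supplies clamp bounds).
#' @param strict fail instead of degrading when any node is masked.
#' @return a `fed_result`: list with `value` (pooled statistic), `n` (total
#'   contributing records), `messages`, `masked` (node ids) and `query`
#'   metadata.
#' @export
#' @examples
#' nodes <- as_nodes(build_fixture(seed = 1))
#' run_query(nodes, "creatinemia", "mean", filter = period == "before")$value
run_query <- function(nodes, variable,
                      statistic = c("count", "sum", "mean", "sd", "min", "max",
                                    "quantile", "percentiles", "histogram"),
                      filter = NULL, by = NULL,
                      dp = c("none", "local", "central"), epsilon = NULL,
                      q = 0.5, policy = disclosure_policy(), stream = NULL,
                      ledger = NULL, config = study_config(), strict = FALSE) {
  statistic <- match.arg(statistic)
  dp <- match.arg(dp)
  filter_quo <- rlang::enquo(filter)
  if (dp != "none" && (is.null(epsilon) || epsilon <= 0)) {
    stop("dp queries require a positive epsilon", call. = FALSE)
  }
  if (dp != "none" && is.null(stream)) {
    stop("dp queries require a dp_stream", call. = FALSE)
  }
  if (dp == "none" && statistic %in% c("min", "max")) {
    stop("extrema are disclosive and only released under DP", call. = FALSE)
  }
  if (dp == "central" && statistic %in% c("quantile", "percentiles")) {
    stop("central DP is not defined for rank statistics here; use dp = \"local\"",
         call. = FALSE)
  }
  for (nd in nodes) {
    if (!all(cohort_columns() %in% names(nd)) && !(variable %in% names(nd))) {
      stop("schema mismatch: node lacks variable ", variable, call. = FALSE)
    }
    if (!(variable %in% names(nd))) {
      stop("schema mismatch: node lacks variable ", variable, call. = FALSE)
    }
  }
  bounds <- if (statistic %in% c("sum", "mean", "sd", "min", "max",
                                 "quantile", "percentiles")) {
    schema_bounds(config$schema, variable)
  }
  categories <- if (statistic == "histogram") {
    lv <- levels(factor(nodes[[1]][[variable]]))
    sch_row <- which(config$schema$name == variable)
    if (length(sch_row) == 1 && !is.null(config$schema$categories[[sch_row]])) {
      lv <- config$schema$categories[[sch_row]]
    }
    if (variable == "period") lv <- c("before", "after")
    lv
  }
  by_categories <- if (!is.null(by)) {
    if (by == "period") c("before", "after") else {
      sch_row <- which(config$schema$name == by)
      if (length(sch_row) == 1 && !is.null(config$schema$categories[[sch_row]])) {
        config$schema$categories[[sch_row]]
      } else levels(factor(nodes[[1]][[by]]))
    }
  }
  grid <- c(0.05, 0.25, 0.5, 0.75, 0.95)

  messages <- lapply(names(nodes), function(id) {
    df <- filter_nodes(nodes[id], filter_quo)[[1]]
    x <- df[[variable]]
    x_ok <- x[!is.na(x)]
    n_loc <- length(x_ok)
    local_cells <- NULL
    if (statistic == "histogram") {
      local_cells <- if (is.null(by)) {
        table(factor(x_ok, levels = categories))
      } else {
        table(factor(x, levels = categories),
              factor(df[[by]], levels = by_categories))
      }
    }
    status <- if (statistic == "histogram") {
      check_disclosure(as.numeric(local_cells), policy, is_cells = TRUE)
    } else {
      check_disclosure(n_loc, policy, is_cells = FALSE)
    }
    if (status == "masked") {
      return(aggregate_message(id, NA_real_, statistic, status = "masked"))
    }
    noisy <- dp == "local"
    charge <- function(stat, eps) if (noisy) charge_ledger(ledger, id, stat, eps)
    xc <- if (!is.null(bounds) && dp != "none") clamp(x_ok, bounds) else x_ok
    payload <- switch(
      statistic,
      count = {
        charge("count", epsilon)
        v <- if (noisy) laplace_release(n_loc, epsilon, 1, stream) else n_loc
        list(count = v)
      },
      sum = {
        charge("sum", epsilon)
        v <- if (noisy) laplace_release(sum(xc), epsilon, max(abs(bounds)), stream) else sum(xc)
        list(sum = v)
      },
      mean = {
        charge("mean.sum", epsilon / 2); charge("mean.count", epsilon / 2)
        s <- sum(xc); n2 <- n_loc
        if (noisy) {
          s <- laplace_release(s, epsilon / 2, max(abs(bounds)), stream)
          n2 <- laplace_release(n2, epsilon / 2, 1, stream)
        }
        list(sum = s, count = n2)
      },
      sd = {
        for (p in c("sd.count", "sd.sum", "sd.sumsq")) charge(p, epsilon / 3)
        n2 <- n_loc; s <- sum(xc); ss <- sum(xc^2)
        if (noisy) {
          n2 <- laplace_release(n2, epsilon / 3, 1, stream)
          s <- laplace_release(s, epsilon / 3, max(abs(bounds)), stream)
          ss <- laplace_release(ss, epsilon / 3, max(bounds^2), stream)
        }
        list(count = n2, sum = s, sumsq = ss)
      },
      min = ,
      max = {
        v <- if (noisy) {
          dp_extremum(x_ok, bounds, epsilon, which = statistic,
                      stream = stream, ledger = ledger, node = id)
        } else if (statistic == "min") min(clamp(x_ok, bounds)) else max(clamp(x_ok, bounds))
        stats::setNames(list(v), statistic)
      },
      quantile = {
        v <- if (noisy) {
          dp_quantile(x_ok, bounds, q, epsilon, stream, ledger = ledger, node = id)
        } else unname(stats::quantile(x_ok, q, type = 7))
        list(quantile = v, count = n_loc)
      },
      percentiles = {
        v <- if (noisy) {
          vapply(grid, function(p) {
            dp_quantile(x_ok, bounds, p, epsilon / length(grid), stream,
                        ledger = ledger, node = id)
          }, numeric(1))
        } else unname(stats::quantile(x_ok, grid, type = 7))
        list(quantiles = stats::setNames(v, paste0("p", grid * 100)),
             count = n_loc)
      },
      histogram = {
        cells <- local_cells
        if (noisy) {
          charge("histogram", epsilon)
          flat <- as.numeric(cells)
          if (!stream$noise_free) {
            flat <- pmax(round(flat + stream_laplace(stream, length(flat), 1 / epsilon)), 0)
          }
          cells[] <- flat
        }
        list(cells = unclass(cells))
      })
    aggregate_message(id, n_loc, statistic, payload,
                      epsilon = if (noisy) epsilon else NA_real_, status = "ok")
  })
  names(messages) <- names(nodes)
  masked <- names(nodes)[vapply(messages, function(m) m$status == "masked", logical(1))]
  ok <- messages[setdiff(names(nodes), masked)]
  if (length(ok) == 0) {
    stop("all nodes masked the query; nothing to pool", call. = FALSE)
  }
  if (strict && length(masked) > 0) {
    stop("strict mode: node(s) masked the query: ",
         paste(masked, collapse = ", "), call. = FALSE)
  }
  pooled <- pool_messages(ok, statistic, grid)
  if (dp == "central") {
    pooled <- central_noise(pooled, ok, statistic, epsilon, bounds, stream, ledger)
  }
  structure(list(value = pooled$value, n = pooled$n, messages = messages,
                 masked = masked,
                 query = list(variable = variable, statistic = statistic,
                              dp = dp, epsilon = epsilon)),
            class = "fed_result")
}

pool_messages <- function(ok, statistic, grid) {
  pay <- function(field) vapply(ok, function(m) m$payload[[field]], numeric(1))
  n_tot <- sum(vapply(ok, function(m) m$n, numeric(1)))
  value <- switch(
    statistic,
    count = sum(pay("count")),
    sum = sum(pay("sum")),
    mean = sum(pay("sum")) / max(sum(pay("count")), 1),
    sd = {
      n <- max(sum(pay("count")), 2)
      s <- sum(pay("sum")); ss <- sum(pay("sumsq"))
      sqrt(max((ss - s^2 / n) / (n - 1), 0))
    },
    min = min(pay("min")),
    max = max(pay("max")),
    quantile = sum(pay("count") * pay("quantile")) / sum(pay("count")),
    percentiles = pool_quantiles(lapply(ok, function(m) m$payload$quantiles),
                                 pay("count")),
    histogram = pool_table(lapply(ok, function(m) m$payload$cells)))
  list(value = value, n = n_tot)
}

central_noise <- function(pooled, ok, statistic, epsilon, bounds, stream, ledger) {
  ch <- function(stat, eps) charge_ledger(ledger, "coordinator", stat, eps)
  pay <- function(field) sum(vapply(ok, function(m) m$payload[[field]], numeric(1)))
  v <- pooled$value
  pooled$value <- switch(
    statistic,
    count = { ch("count", epsilon); laplace_release(v, epsilon, 1, stream) },
    sum = { ch("sum", epsilon)
      laplace_release(v, epsilon, max(abs(bounds)), stream) },
    mean = {
      ch("mean.sum", epsilon / 2); ch("mean.count", epsilon / 2)
      s <- laplace_release(pay("sum"), epsilon / 2, max(abs(bounds)), stream)
      n <- laplace_release(pay("count"), epsilon / 2, 1, stream)
      s / max(n, 1)
    },
    sd = {
      for (p in c("sd.count", "sd.sum", "sd.sumsq")) ch(p, epsilon / 3)
      n <- max(laplace_release(pay("count"), epsilon / 3, 1, stream), 2)
      s <- laplace_release(pay("sum"), epsilon / 3, max(abs(bounds)), stream)
      ss <- laplace_release(pay("sumsq"), epsilon / 3, max(bounds^2), stream)
      sqrt(max((ss - s^2 / n) / (n - 1), 0))
    },
    min = ,
    max = {
      ch(statistic, epsilon)
      clamp(laplace_release(v, epsilon, diff(bounds), stream), bounds)
    },
    histogram = {
      ch("histogram", epsilon)
      flat <- as.numeric(v)
      if (!stream$noise_free) {
        flat <- pmax(round(flat + stream_laplace(stream, length(flat), 1 / epsilon)), 0)
      }
      v[] <- flat
      v
    })
  pooled
}

#' @export
print.fed_result <- function(x, ...) {
  cat(sprintf("<fed_result> %s(%s), dp=%s, n=%s\n", x$query$statistic,
              x$query$variable, x$query$dp, format(x$n)))
  if (length(x$masked) > 0) {
    cat("  masked nodes:", paste(x$masked, collapse = ", "), "\n")
  }
  print(x$value)
  invisible(x)
}
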