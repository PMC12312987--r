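#' Seeded randomness stream for differentially private releases
#'
#' All DP noise in the package flows through an explicit stream object so
#' that a whole federated run is reproducible from one root seed. The stream
#' fans out deterministic substream seeds by a counter scheme: the i-th draw
#' uses seed `(root * 48271 + i * 9973) mod (2^31 - 1)`, so per-node,
#' per-query noise is independent of evaluation order elsewhere in the
#' session and never touches the caller's global RNG state.
#'
#' `noise_free = TRUE` is a test-only switch under which every mechanism
#' returns its exact (non-private) counterpart while still charging the
#' ledger; it is the epsilon-to-infinity degeneration used to check that the
#' DP pipeline collapses onto the plain pipeline.
#'
#' @param seed integer root seed.
#' @param noise_free logical; suppress all noise (testing only).
#' @return a `dp_stream` object.
#' @export
dp_stream <- function(seed, noise_free = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  env$root <- as.double(seed) %% 2147483647
  env$counter <- 0
  env$noise_free <- isTRUE(noise_free)
  class(env) <- "dp_stream"
  env
}

stream_next_seed <- function(stream) {
  stream$counter <- stream$counter + 1
  as.integer((stream$root * 48271 + stream$counter * 9973) %% 2147483647)
}

# uniforms from a substream, isolated from the session RNG
stream_runif <- function(stream, n) {
  seed <- stream_next_seed(stream)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

# Laplace(0, b) via inverse CDF
stream_laplace <- function(stream, n, scale) {
  if (scale == 0) return(rep(0, n))
  u <- stream_runif(stream, n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Clamp values to public bounds
#'
#' @param x numeric vector.
#' @param bounds length-2 numeric `c(lower, upper)`.
#' @return `x` with every value projected into `[lower, upper]`; missing
#'   values pass through.
#' @export
clamp <- function(x, bounds) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  pmin(pmax(x, bounds[1]), bounds[2])
}

#' Privacy-budget ledger
#'
#' Tracks the cumulative privacy budget spent per (node, dataset) under pure
#' epsilon-DP, where the budget of a sequence of releases is the sum of the
#' budgets of the individual releases (sequential composition). Compound
#' statistics log one entry per sub-release so the audit trail shows how a
#' total was split. Post-processing (rounding, clamping) is free and never
#' appears in the ledger.
#'
#' @return `new_ledger()` returns an empty `budget_ledger`.
#' @export
new_ledger <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  class(env) <- "budget_ledger"
  env
}

#' @rdname new_ledger
#' @param ledger a `budget_ledger` (or `NULL`, in which case charging is a
#'   no-op so mechanisms can be used standalone).
#' @param node node identifier the release came from.
#' @param statistic label of the released statistic (sub-releases use
#'   dotted names, e.g. `"mean.sum"`).
#' @param epsilon budget spent by this release; must be > 0.
#' @export
charge_ledger <- function(ledger, node, statistic, epsilon) {
  if (is.null(ledger)) return(invisible(NULL))
  stopifnot(inherits(ledger, "budget_ledger"), epsilon > 0)
  ledger$entries[[length(ledger$entries) + 1L]] <-
    list(node = as.character(node), statistic = as.character(statistic),
         epsilon = as.double(epsilon))
  invisible(ledger)
}

#' @rdname new_ledger
#' @export
ledger_entries <- function(ledger) {
  if (length(ledger$entries) == 0) {
    return(tibble::tibble(node = character(), statistic = character(),
                          epsilon = double(), cumulative = double()))
  }
  tb <- dplyr::bind_rows(lapply(ledger$entries, tibble::as_tibble))
  tb |>
    dplyr::group_by(.data$node) |>
    dplyr::mutate(cumulative = cumsum(.data$epsilon)) |>
    dplyr::ungroup()
}

#' @rdname new_ledger
#' @export
ledger_total <- function(ledger, node = NULL) {
  tb <- ledger_entries(ledger)
  if (!is.null(node)) tb <- tb[tb$node %in% node, ]
  sum(tb$epsilon)
}

#' @rdname new_ledger
#' @param path output path for a JSON-lines export (one release per line).
#' @export
write_ledger_jsonl <- function(ledger, path) {
  tb <- ledger_entries(ledger)
  lines <- vapply(seq_len(nrow(tb)), function(i) {
    jsonlite::toJSON(as.list(tb[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.budget_ledger <- function(x, ...) {
  tb <- ledger_entries(x)
  cat("<budget_ledger> ", nrow(tb), " release(s), total epsilon ",
      format(sum(tb$epsilon)), "\n", sep = "")
  if (nrow(tb) > 0) print(dplyr::count(tb, .data$node, wt = .data$epsilon,
                                       name = "epsilon_spent"))
  invisible(x)
}

#' The Laplace mechanism
#'
#' Releases `true_value + Laplace(0, b)` with scale `b = sensitivity /
#' epsilon`, the standard calibration under which the release is
#' epsilon-differentially private for a query whose value changes by at most
#' `sensitivity` when one record is added or removed. With zero sensitivity
#' the value is returned exactly.
#'
#' @param true_value numeric scalar to protect.
#' @param epsilon privacy budget (> 0).
#' @param sensitivity query sensitivity in the value's units (>= 0).
#' @param stream a [dp_stream()].
#' @return the noised value.
#' @export
#' @examples
#' s <- dp_stream(42)
#' laplace_release(118, epsilon = 5, sensitivity = 1, stream = s)
laplace_release <- function(true_value, epsilon, sensitivity, stream) {
  stopifnot(epsilon > 0, sensitivity >= 0, is.finite(sensitivity))
  if (stream$noise_free || sensitivity == 0) return(true_value)
  true_value + stream_laplace(stream, 1L, sensitivity / epsilon)
}

#' Differentially private count
#'
#' Laplace release of the number of (non-missing) records with sensitivity 1.
#'
#' @param x vector whose non-missing entries are counted.
#' @param epsilon privacy budget.
#' @param stream a [dp_stream()].
#' @param ledger optional [new_ledger()] to charge.
#' @param node node label for the ledger.
#' @return noisy count (real-valued; round as post-processing if needed).
#' @export
dp_count <- function(x, epsilon, stream, ledger = NULL, node = "node") {
  n <- sum(!is.na(x))
  charge_ledger(ledger, node, "count", epsilon)
  laplace_release(n, epsilon, 1, stream)
}

#' Differentially private mean
#'
#' Clamps the values to the public bounds, then releases
#' `noisy_sum / noisy_count` with the budget split evenly between the two
#' sub-releases: the sum at sensitivity `max(|L|, |U|)` and the count at
#' sensitivity 1, each at `epsilon / 2`. The noisy denominator is floored at
#' 1 (post-processing) so the ratio is always defined.
#'
#' @inheritParams dp_count
#' @param bounds public clamp bounds `c(L, U)`.
#' @return noisy mean.
#' @export
dp_mean <- function(x, bounds, epsilon, stream, ledger = NULL, node = "node") {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("dp_mean: all values missing", call. = FALSE)
  x <- clamp(x, bounds)
  charge_ledger(ledger, node, "mean.sum", epsilon / 2)
  charge_ledger(ledger, node, "mean.count", epsilon / 2)
  s <- laplace_release(sum(x), epsilon / 2, max(abs(bounds)), stream)
  n <- laplace_release(length(x), epsilon / 2, 1, stream)
  s / max(n, 1)
}

#' Differentially private variance and standard deviation
#'
#' Built from three noisy aggregates - count, sum and sum of squares - each
#' at `epsilon / 3` (sum-of-squares sensitivity `max(L^2, U^2)`). The
#' plug-in sample variance `(ssq - s^2/n) / (n - 1)` is floored at zero
#' before any square root, both floors being free post-processing.
#'
#' @inheritParams dp_mean
#' @return noisy sample variance (`dp_variance`) or its square root
#'   (`dp_sd`).
#' @export
dp_variance <- function(x, bounds, epsilon, stream, ledger = NULL, node = "node") {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("dp_variance: need at least 2 non-missing values", call. = FALSE)
  x <- clamp(x, bounds)
  for (part in c("variance.count", "variance.sum", "variance.sumsq")) {
    charge_ledger(ledger, node, part, epsilon / 3)
  }
  n <- laplace_release(length(x), epsilon / 3, 1, stream)
  s <- laplace_release(sum(x), epsilon / 3, max(abs(bounds)), stream)
  ssq <- laplace_release(sum(x^2), epsilon / 3, max(bounds^2), stream)
  n <- max(n, 2)
  max((ssq - s^2 / n) / (n - 1), 0)
}

#' @rdname dp_variance
#' @export
dp_sd <- function(x, bounds, epsilon, stream, ledger = NULL, node = "node") {
  sqrt(dp_variance(x, bounds, epsilon, stream, ledger, node))
}

#' Differentially private minimum or maximum
#'
#' Unlike the plain federated pipeline, where extrema are withheld as
#' disclosive, the DP pipeline can release them: the clamped true extremum
#' plus Laplace noise at sensitivity `U - L`, re-clamped into `[L, U]` as
#' post-processing.
#'
#' @inheritParams dp_mean
#' @param which `"min"` or `"max"`.
#' @return noisy extremum, always within the bounds.
#' @export
dp_extremum <- function(x, bounds, epsilon, stream, which = c("min", "max"),
                        ledger = NULL, node = "node") {
  which <- match.arg(which)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("dp_extremum: all values missing", call. = FALSE)
  v <- if (which == "min") min(clamp(x, bounds)) else max(clamp(x, bounds))
  charge_ledger(ledger, node, which, epsilon)
  clamp(laplace_release(v, epsilon, diff(bounds), stream), bounds)
}

#' Differentially private quantile (exponential mechanism)
#'
#' Releases a quantile by the exponential mechanism over the clamped value
#' domain: between consecutive sorted values the utility is
#' `u(x) = -|#\{values < x\} - q n|`, an interval is sampled with probability
#' proportional to its length times `exp(epsilon u / 2)`, and a point is
#' drawn uniformly within it. This is far less destructive for medians than
#' Laplace noise at sensitivity `U - L` would be. In noise-free mode the
#' exact type-7 sample quantile is returned.
#'
#' @inheritParams dp_mean
#' @param q probability in (0, 1).
#' @return noisy quantile, always within the bounds.
#' @export
dp_quantile <- function(x, bounds, q, epsilon, stream, ledger = NULL,
                        node = "node") {
  stopifnot(q > 0, q < 1)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("dp_quantile: all values missing", call. = FALSE)
  charge_ledger(ledger, node, paste0("quantile.", q), epsilon)
  x <- clamp(x, bounds)
  if (stream$noise_free) {
    return(clamp(unname(stats::quantile(x, q, type = 7)), bounds))
  }
  n <- length(x)
  z <- c(bounds[1], sort(x), bounds[2])
  width <- diff(z)                       # n + 1 intervals
  utility <- -abs(0:n - q * n)           # records strictly below interval i
  logw <- log(pmax(width, 0)) + epsilon * utility / 2
  keep <- is.finite(logw)
  if (!any(keep)) return(unname(stats::quantile(x, q, type = 1)))
  logw <- logw - max(logw[keep])
  w <- ifelse(keep, exp(logw), 0)
  u <- stream_runif(stream, 2L)
  i <- findInterval(u[1] * sum(w), cumsum(w)) + 1L
  i <- min(i, length(width))
  z[i] + u[2] * width[i]
}

#' Differentially private histogram
#'
#' Adds independent `Laplace(1/epsilon)` noise to each bin of a categorical
#' count vector. Because the bins partition the records, parallel
#' composition applies: the whole table costs `epsilon`, not
#' `epsilon x bins`. Released counts are rounded to the nearest non-negative
#' integer (free post-processing).
#'
#' @inheritParams dp_count
#' @param x categorical vector (values must lie in `categories`).
#' @param categories the fixed, public category list.
#' @return named integer vector of noisy bin counts.
#' @export
dp_histogram <- function(x, categories, epsilon, stream, ledger = NULL,
                         node = "node") {
  x <- x[!is.na(x)]
  if (!all(x %in% categories)) {
    stop("dp_histogram: value outside the declared categories: ",
         paste(unique(setdiff(x, categories)), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(x, levels = categories))
  charge_ledger(ledger, node, "histogram", epsilon)
  if (stream$noise_free) {
    out <- as.integer(counts)
  } else {
    noisy <- as.numeric(counts) + stream_laplace(stream, length(counts), 1 / epsilon)
    out <- pmax(as.integer(round(noisy)), 0L)
  }
  stats::setNames(out, categories)
}
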