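node_design <- function(df, formula, response = NULL) {
  vars <- all.vars(formula)
  keep <- stats::complete.cases(df[, c(response, vars), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  X <- stats::model.matrix(formula, data = df)
  list(X = X, df = df, n = nrow(df))
}

#' Federated linear regression by sufficient-statistic sharing
#'
#' Each node computes `X'X`, `X'y`, `y'y` and its complete-case count on the
#' shared design (reference-level dummy coding with levels fixed by the
#' schema, so columns align across nodes); the coordinator sums these and
#' solves the normal equations. The result is numerically the centralized
#' least-squares fit on the concatenated data, but no record-level data ever
#' leaves a node. 95% CIs use t quantiles on `N - p` degrees of freedom.
#'
#' @param nodes named list of per-center cohort tibbles.
#' @param formula model formula, e.g.
#'   `firstline_duration_days ~ period + treatment_category`.
#' @return a `fed_fit` object (`kind = "ols"`); see [tidy.fed_fit()].
#' @export
#' @examples
#' nodes <- lapply(as_nodes(build_fixture(seed = 1)), derive_outcome)
#' fit <- fed_ols(nodes, firstline_duration_days ~ period)
#' tidy(fit)
fed_ols <- function(nodes, formula) {
  response <- all.vars(formula)[1]
  rhs <- stats::delete.response(stats::terms(formula))
  pieces <- lapply(nodes, function(df) {
    d <- node_design(df, rhs, response = response)
    y <- d$df[[response]]
    list(XtX = crossprod(d$X), Xty = crossprod(d$X, y),
         yty = sum(y^2), n = d$n)
  })
  XtX <- Reduce(`+`, lapply(pieces, `[[`, "XtX"))
  Xty <- Reduce(`+`, lapply(pieces, `[[`, "Xty"))
  yty <- sum(vapply(pieces, `[[`, numeric(1), "yty"))
  N <- sum(vapply(pieces, `[[`, numeric(1), "n"))
  p <- ncol(XtX)
  if (N <= p) stop("fewer complete cases than design columns", call. = FALSE)
  # scale columns to unit diagonal before solving (conditioning)
  d <- sqrt(diag(XtX))
  if (any(d == 0)) {
    stop("rank-deficient design; empty column(s): ",
         paste(colnames(XtX)[d == 0], collapse = ", "), call. = FALSE)
  }
  A <- XtX / tcrossprod(d)
  qrA <- qr(A)
  if (qrA$rank < p) {
    bad <- colnames(XtX)[qrA$pivot[(qrA$rank + 1):p]]
    stop("singular pooled X'X; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- solve(A, Xty[, 1] / d) / d
  rss <- max(yty - 2 * sum(beta * Xty) + drop(t(beta) %*% XtX %*% beta), 0)
  sigma2 <- rss / (N - p)
  cov <- sigma2 * (solve(A) / tcrossprod(d))
  se <- sqrt(diag(cov))
  tq <- stats::qt(0.975, N - p)
  new_fed_fit(kind = "ols",
              term = colnames(XtX), estimate = unname(beta),
              std.error = unname(se),
              conf.low = unname(beta - tq * se),
              conf.high = unname(beta + tq * se),
              cov = cov, n = N, df_residual = N - p, sigma = sqrt(sigma2),
              converged = TRUE, iterations = 0L, formula = formula)
}

# Breslow-ties gradient/Hessian of one stratum's log partial likelihood.
# Sorted descending by time, so risk-set aggregates S0 = sum(w),
# S1 = sum(w x) and S2 = sum(w x x') over each risk set are cumulative sums.
cox_stratum_derivs <- function(X, time, status, beta) {
  ord <- order(-time)
  X <- X[ord, , drop = FALSE]
  time <- time[ord]
  status <- status[ord]
  p <- ncol(X)
  n <- nrow(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  S0 <- cumsum(w)
  cum <- function(m) {
    out <- apply(m, 2, cumsum)
    if (n == 1) out <- matrix(out, nrow = 1)
    out
  }
  S1 <- cum(X * w)
  XXw <- matrix(0, n, p * p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    XXw[, (a - 1) * p + b] <- X[, a] * X[, b] * w
  }
  S2 <- cum(XXw)
  loglik <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  ev <- which(status == 1)
  if (length(ev) == 0) return(list(loglik = 0, grad = grad, hess = hess, events = 0))
  # last row sharing the event's time: ties belong to the same risk set
  last_of_time <- vapply(ev, function(i) max(which(time == time[i])), integer(1))
  for (k in seq_along(ev)) {
    i <- ev[k]
    r <- last_of_time[k]
    s0 <- S0[r]
    s1 <- S1[r, ]
    s2 <- matrix(S2[r, ], p, p)
    loglik <- loglik + eta[i] - log(s0)
    grad <- grad + X[i, ] - s1 / s0
    hess <- hess + s2 / s0 - tcrossprod(s1 / s0)
  }
  list(loglik = loglik, grad = grad, hess = hess, events = length(ev))
}

#' Federated Cox proportional hazards model, stratified by center
#'
#' Fits a Cox model whose baseline hazard is stratified by node, so risk
#' sets never cross centers and the only quantities exchanged per
#' Newton-Raphson iteration are each node's gradient vector and Hessian
#' matrix of its stratum's log partial likelihood (Breslow tie handling).
#' The coordinator runs Newton-Raphson with step halving from beta = 0 to a
#' gradient norm below 1e-8 (at most 50 iterations). Hazard ratios and 95%
#' CIs come from `exp(beta +/- 1.96 se)`.
#'
#' @param nodes named list of per-center cohort tibbles that already carry
#'   outcome columns (`time_days`, `event`; see [derive_outcome()]), or raw
#'   cohorts (outcomes are derived with `config`).
#' @param formula one-sided covariate formula, e.g.
#'   `~ period + treatment_category`.
#' @param config a [study_config()] used when outcomes must be derived.
#' @return a `fed_fit` object (`kind = "cox"`).
#' @export
#' @examples
#' nodes <- as_nodes(build_fixture(seed = 1))
#' fit <- fed_cox(nodes, ~ period)
#' tidy(fit, exponentiate = TRUE)
fed_cox <- function(nodes, formula, config = study_config()) {
  nodes <- lapply(nodes, function(df) {
    if (!all(c("time_days", "event") %in% names(df))) {
      df <- derive_outcome(df, config)
    }
    df
  })
  tt <- stats::delete.response(stats::terms(formula))
  strata <- lapply(nodes, function(df) {
    vars <- all.vars(tt)
    keep <- stats::complete.cases(df[, c(vars, "time_days", "event"), drop = FALSE])
    df <- df[keep, , drop = FALSE]
    X <- stats::model.matrix(tt, data = df)
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
    list(X = X, time = df$time_days,
         status = as.integer(df$event == "progressed"), n = nrow(df))
  })
  p <- ncol(strata[[1]]$X)
  if (p == 0) stop("empty covariate set for the Cox model", call. = FALSE)
  total_events <- sum(vapply(strata, function(s) sum(s$status), numeric(1)))
  if (total_events == 0) stop("no events in any stratum", call. = FALSE)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  prev_ll <- -Inf
  hess <- diag(p)
  for (iter in seq_len(50L)) {
    parts <- lapply(strata, function(s) {
      cox_stratum_derivs(s$X, s$time, s$status, beta)
    })
    ll <- sum(vapply(parts, `[[`, numeric(1), "loglik"))
    grad <- Reduce(`+`, lapply(parts, `[[`, "grad"))
    hess <- Reduce(`+`, lapply(parts, `[[`, "hess"))
    if (sqrt(sum(grad^2)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(hess, grad), error = function(e) {
      stop("singular information matrix in the Cox fit", call. = FALSE)
    })
    # step-halving safeguard against overshoot
    for (h in 0:10) {
      cand <- beta + step / 2^h
      ll_cand <- sum(vapply(strata, function(s) {
        cox_stratum_derivs(s$X, s$time, s$status, cand)$loglik
      }, numeric(1)))
      if (ll_cand >= ll - 1e-12) break
    }
    beta <- cand
    prev_ll <- ll
  }
  cov <- solve(hess)
  se <- sqrt(diag(cov))
  nm <- colnames(strata[[1]]$X)
  new_fed_fit(kind = "cox",
              term = nm, estimate = unname(beta), std.error = unname(se),
              conf.low = unname(beta - 1.96 * se),
              conf.high = unname(beta + 1.96 * se),
              cov = cov, n = sum(vapply(strata, `[[`, numeric(1), "n")),
              df_residual = NA_real_, sigma = NA_real_,
              converged = converged, iterations = iter, formula = formula,
              events = total_events)
}

new_fed_fit <- function(kind, term, estimate, std.error, conf.low, conf.high,
                        cov, n, df_residual, sigma, converged, iterations,
                        formula, events = NA_real_) {
  structure(list(kind = kind,
                 coefficients = tibble::tibble(
                   term = term, estimate = estimate, std.error = std.error,
                   conf.low = conf.low, conf.high = conf.high),
                 cov = cov, n = n, df_residual = df_residual, sigma = sigma,
                 converged = converged, iterations = iterations,
                 formula = formula, events = events),
            class = "fed_fit")
}

#' @export
print.fed_fit <- function(x, ...) {
  cat(sprintf("<fed_fit> %s, n = %s%s, %s\n", toupper(x$kind), x$n,
              if (!is.na(x$events)) paste0(", events = ", x$events) else "",
              if (x$converged) sprintf("converged in %d iteration(s)", x$iterations)
              else "DID NOT CONVERGE"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a federated model fit
#'
#' broom-style one-row-per-term summary. For Cox fits,
#' `exponentiate = TRUE` returns hazard ratios with their CIs.
#'
#' @param x a `fed_fit`.
#' @param exponentiate exponentiate estimates and CI bounds.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy fed_fit
#' @export
tidy.fed_fit <- function(x, exponentiate = FALSE, ...) {
  tb <- x$coefficients
  if (exponentiate) {
    tb$estimate <- exp(tb$estimate)
    tb$conf.low <- exp(tb$conf.low)
    tb$conf.high <- exp(tb$conf.high)
  }
  tb
}

#' @rdname tidy.fed_fit
#' @method glance fed_fit
#' @export
glance.fed_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$n, events = x$events,
                 df_residual = x$df_residual, sigma = x$sigma,
                 converged = x$converged, iterations = x$iterations)
}

#' Coefficient significance by confidence interval
#'
#' The study's decision rule: a coefficient is significant when its 95% CI
#' excludes the null value. The natural null is 0 on the linear-regression
#' scale and 1 on the hazard-ratio scale; the default picks the right one
#' from the fit kind (Cox fits are judged after exponentiation).
#'
#' @param fit a `fed_fit`.
#' @param null_value the null to test against; defaults to 0 for OLS and 1
#'   for hazard ratios.
#' @return a tibble: `term`, `conf.low`, `conf.high`, `significant`.
#' @export
significance_by_ci <- function(fit, null_value = NULL) {
  stopifnot(inherits(fit, "fed_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  tb <- tidy(fit, exponentiate = fit$kind == "cox")
  if (is.null(null_value)) null_value <- if (fit$kind == "cox") 1 else 0
  tibble::tibble(term = tb$term, conf.low = tb$conf.low,
                 conf.high = tb$conf.high,
                 significant = tb$conf.low > null_value | tb$conf.high < null_value)
}

#' Forest plot of a federated model fit
#'
#' @param object a `fed_fit`.
#' @param ... unused.
#' @return a ggplot object (hazard-ratio scale for Cox fits).
#' @method autoplot fed_fit
#' @export
autoplot.fed_fit <- function(object, ...) {
  expo <- object$kind == "cox"
  tb <- tidy(object, exponentiate = expo)
  null_value <- if (expo) 1 else 0
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = null_value, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = if (expo) "Hazard ratio (95% CI)" else "Estimate (95% CI)",
                  y = NULL,
                  title = sprintf("Federated %s fit (n = %s)",
                                  toupper(object$kind), object$n)) +
    ggplot2::theme_minimal()
}
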