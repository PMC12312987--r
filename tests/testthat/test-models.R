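random_nodes <- function(seed, n_centers = 3) {
  # small random cohorts with heterogeneous centers for oracle comparisons
  isolate <- get("isolate_seed", asNamespace("fedstats"))
  isolate(seed, {
    nodes <- lapply(seq_len(n_centers), function(i) {
      n <- sample(30:60, 1)
      tibble::tibble(
        center = paste0("c", i),
        period = factor(sample(c("before", "after"), n, replace = TRUE),
                        levels = c("before", "after")),
        x = rnorm(n),
        firstline_duration_days = pmax(rnorm(n, 200 + 30 * (i - 1), 80), 1),
        time_days = round(pmin(rweibull(n, 1.1, 400), 730), 1),
        event = ifelse(runif(n) < 0.75, "progressed", "censored"))
    })
    names(nodes) <- paste0("c", seq_len(n_centers))
    nodes
  })
}

test_that("a perfectly linear response is recovered exactly", {
  nodes <- lapply(1:3, function(i) {
    tibble::tibble(center = paste0("c", i), x = rnorm(20, i),
                   y = numeric(20))
  })
  names(nodes) <- paste0("c", 1:3)
  nodes <- lapply(nodes, function(df) { df$y <- 2 + 3 * df$x; df })
  fit <- fed_ols(nodes, y ~ x)
  expect_equal(tidy(fit)$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-8)
})

test_that("federated OLS equals centralized least squares", {
  for (seed in c(3, 17, 42)) {
    nodes <- random_nodes(seed)
    fit <- fed_ols(nodes, firstline_duration_days ~ period + x)
    pooled <- dplyr::bind_rows(nodes)
    ora <- lm(firstline_duration_days ~ period + x, data = pooled)
    expect_equal(tidy(fit)$estimate, unname(coef(ora)), tolerance = 1e-8)
    ci <- confint(ora)
    expect_equal(tidy(fit)$conf.low, unname(ci[, 1]), tolerance = 1e-6)
    expect_equal(tidy(fit)$conf.high, unname(ci[, 2]), tolerance = 1e-6)
    expect_equal(fit$sigma, summary(ora)$sigma, tolerance = 1e-8)
  }
})

test_that("a duplicated design column raises a singularity error", {
  nodes <- random_nodes(5)
  nodes <- lapply(nodes, function(df) { df$x2 <- df$x; df })
  expect_error(fed_ols(nodes, firstline_duration_days ~ x + x2),
               "collinear|singular")
})

test_that("OLS recovers a known period effect within Monte-Carlo error", {
  isolate <- get("isolate_seed", asNamespace("fedstats"))
  gamma <- 60
  ests <- isolate(7, vapply(1:30, function(i) {
    nodes <- lapply(1:3, function(k) {
      per <- factor(rep(c("before", "after"), each = 25),
                    levels = c("before", "after"))
      tibble::tibble(center = paste0("c", k), period = per,
                     y = 180 + gamma * (per == "after") + rnorm(50, 0, 80))
    })
    names(nodes) <- paste0("c", 1:3)
    tidy(fed_ols(nodes, y ~ period))$estimate[2]
  }, numeric(1)))
  se_mc <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - gamma), 4 * se_mc + 1)
})

test_that("the toy Cox fit matches direct partial-likelihood maximization", {
  # four subjects, one binary covariate; the stratum log partial likelihood
  # is written out term by term and maximized independently
  time <- c(1, 2, 3, 4); status <- c(1, 1, 0, 1); x <- c(1, 0, 1, 0)
  logpl <- function(b) {
    risk <- function(ids) sum(exp(b * x[ids]))
    (b * x[1] - log(risk(1:4))) + (b * x[2] - log(risk(2:4))) +
      (b * x[4] - log(risk(4)))
  }
  ora <- optimize(logpl, c(-5, 5), maximum = TRUE)$maximum
  nodes <- list(A = tibble::tibble(center = "A", time_days = time,
                                   event = ifelse(status == 1, "progressed",
                                                  "censored"),
                                   x = x))
  fit <- fed_cox(nodes, ~ x)
  expect_equal(tidy(fit)$estimate, ora, tolerance = 1e-5)
})

test_that("the stratified federated Cox fit equals the reference fit", {
  for (seed in c(4, 23, 31)) {
    nodes <- random_nodes(seed)
    fit <- fed_cox(nodes, ~ period + x)
    pooled <- dplyr::bind_rows(nodes)
    ora <- survival::coxph(
      survival::Surv(time_days, event == "progressed") ~ period + x +
        survival::strata(center),
      data = pooled, ties = "breslow")
    expect_equal(tidy(fit)$estimate, unname(coef(ora)), tolerance = 1e-6)
    expect_equal(tidy(fit)$std.error,
                 unname(sqrt(diag(vcov(ora)))), tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("Cox ties are handled the Breslow way", {
  nodes <- list(A = tibble::tibble(
    center = "A",
    time_days = c(2, 2, 2, 5, 5, 7, 9, 9),
    event = c("progressed", "progressed", "censored", "progressed",
              "progressed", "censored", "progressed", "progressed"),
    x = c(1, 0, 1, 0, 1, 0, 1, 0)))
  fit <- fed_cox(nodes, ~ x)
  ora <- survival::coxph(
    survival::Surv(time_days, event == "progressed") ~ x,
    data = nodes$A, ties = "breslow")
  expect_equal(tidy(fit)$estimate, unname(coef(ora)), tolerance = 1e-6)
})

test_that("a null covariate's hazard-ratio CI covers 1 at nominal rate", {
  isolate <- get("isolate_seed", asNamespace("fedstats"))
  covered <- isolate(11, vapply(1:100, function(i) {
    nodes <- lapply(1:2, function(k) {
      n <- 150
      tibble::tibble(center = paste0("c", k),
                     time_days = round(pmin(rweibull(n, 1, 350), 730), 2),
                     event = ifelse(rweibull(n, 1, 350) < 730 & runif(n) < .9,
                                    "progressed", "censored"),
                     x = rbinom(n, 1, 0.5))
    })
    names(nodes) <- paste0("c", 1:2)
    ci <- tidy(fed_cox(nodes, ~ x), exponentiate = TRUE)
    ci$conf.low[1] <= 1 && ci$conf.high[1] >= 1
  }, logical(1)))
  expect_gte(mean(covered), 0.9)
})

test_that("per-iteration Cox messages are p-vectors and p x p matrices only", {
  nodes <- random_nodes(2)
  tt <- terms(~ period + x)
  s <- nodes[[1]]
  X <- model.matrix(tt, data = s)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  d <- fedstats:::cox_stratum_derivs(X, s$time_days,
                                     as.integer(s$event == "progressed"),
                                     numeric(ncol(X)))
  p <- ncol(X)
  expect_length(d$grad, p)
  expect_equal(dim(d$hess), c(p, p))
  expect_length(d$loglik, 1)
})

test_that("no events anywhere is an error", {
  nodes <- random_nodes(3)
  nodes <- lapply(nodes, function(df) { df$event <- "censored"; df })
  expect_error(fed_cox(nodes, ~ x), "events")
})

test_that("CI-based significance uses the right null per model kind", {
  nodes <- random_nodes(12)
  ols <- fed_ols(nodes, firstline_duration_days ~ period + x)
  cox <- fed_cox(nodes, ~ period + x)
  s_ols <- significance_by_ci(ols)
  s_cox <- significance_by_ci(cox)
  # agreement with the direct CI checks
  td <- tidy(ols)
  expect_equal(s_ols$significant,
               td$conf.low > 0 | td$conf.high < 0)
  th <- tidy(cox, exponentiate = TRUE)
  expect_equal(s_cox$significant,
               th$conf.low > 1 | th$conf.high < 1)
  # published CIs: both straddle their null
  expect_false(1 < 0.65 || 1 > 1.46)           # HR CI (0.65, 1.46)
  fake <- ols
  fake$coefficients <- tibble::tibble(term = c("a", "b"),
                                      estimate = c(-13.84, 1.5),
                                      std.error = c(1, 1),
                                      conf.low = c(-103.82, 1.1),
                                      conf.high = c(76.14, 2.0))
  sg <- significance_by_ci(fake)
  expect_equal(sg$significant, c(FALSE, TRUE))
})

test_that("tidy, glance and autoplot work on both fit kinds", {
  nodes <- random_nodes(21)
  ols <- fed_ols(nodes, firstline_duration_days ~ x)
  cox <- fed_cox(nodes, ~ x)
  expect_tibble(tidy(ols))
  expect_tibble(glance(cox))
  expect_equal(glance(ols)$kind, "ols")
  expect_gt(glance(cox)$events, 0)
  hr <- tidy(cox, exponentiate = TRUE)
  expect_equal(hr$estimate, exp(tidy(cox)$estimate))
  p <- autoplot(cox)
  expect_s3_class(p, "ggplot")
})
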