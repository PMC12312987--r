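test_that("disclosure check masks small nonzero cells and tiny subsets", {
  pol <- disclosure_policy()
  expect_equal(check_disclosure(c(2, 40), pol), "masked")
  expect_equal(check_disclosure(c(3, 40), pol), "ok")   # inclusive threshold
  expect_equal(check_disclosure(c(0, 40), pol), "ok")   # empty cells allowed
  expect_equal(check_disclosure(0, pol, is_cells = FALSE), "masked")
  expect_equal(check_disclosure(2, pol, is_cells = FALSE), "masked")
  expect_equal(check_disclosure(3, pol, is_cells = FALSE), "ok")
})

test_that("masking is monotone in the threshold", {
  cells <- matrix(c(0, 3, 5, 7, 12, 4), 2)
  for (thr in 1:4) {
    lo <- check_disclosure(cells, disclosure_policy(min_cell_count = thr))
    hi <- check_disclosure(cells, disclosure_policy(min_cell_count = thr + 1))
    expect_false(lo == "masked" && hi == "ok")
  }
})

test_that("pooled means reproduce the published combined summaries", {
  expect_equal(round(pool_mean(tibble::tibble(n = c(75, 74),
                                              mean = c(179.7, 255.2))), 1),
               217.2)
  expect_equal(round(pool_mean(tibble::tibble(n = c(75, 73),
                                              mean = c(66.7, 64.3))), 1),
               65.5)
  expect_equal(pool_mean(tibble::tibble(n = 10, mean = 3.3)), 3.3)
  expect_error(pool_mean(tibble::tibble(n = numeric(0), mean = numeric(0))))
})

test_that("pooled sd equals the sd of the concatenated raw data", {
  set.seed(8)
  for (rep in 1:10) {
    parts <- lapply(1:3, function(i) rnorm(sample(5:40, 1), mean = rnorm(1, 0, 5)))
    msgs <- tibble::tibble(n = lengths(parts),
                           mean = vapply(parts, mean, numeric(1)),
                           sd = vapply(parts, sd, numeric(1)))
    expect_equal(pool_sd(msgs), sd(unlist(parts)), tolerance = 1e-10)
  }
  one <- tibble::tibble(n = 12, mean = 4, sd = 2.5)
  expect_equal(pool_sd(one), 2.5)
  # equal means: only the weighted within-node term survives
  two <- tibble::tibble(n = c(10, 10), mean = c(5, 5), sd = c(2, 2))
  expect_equal(pool_sd(two), sqrt((9 * 4 + 9 * 4) / 19))
})

test_that("table pooling sums cells and rejects mismatched categories", {
  z <- matrix(0, 2, 2, dimnames = list(c("No", "Yes"), c("before", "after")))
  expect_equal(pool_table(list(z, z, z)), z)
  a <- z; a[] <- c(1, 2, 3, 4)
  b <- z; b[] <- c(10, 0, 0, 10)
  expect_equal(as.vector(pool_table(list(a, b))), c(11, 2, 3, 14))
  bad <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("before", "after")))
  expect_error(pool_table(list(a, bad)), "differ")
})

test_that("quantile pooling weights nodes by size on a shared grid", {
  q1 <- c(p25 = 1, p50 = 2, p75 = 3)
  q2 <- c(p25 = 3, p50 = 4, p75 = 5)
  expect_equal(pool_quantiles(list(q1), 10), q1)
  expect_equal(unname(pool_quantiles(list(q1, q2), c(1, 3))["p50"]), 3.5)
  expect_equal(pool_quantiles(list(q1, q2), c(1, 0)), q1)
  expect_error(pool_quantiles(list(q1, c(p5 = 1, p50 = 2, p75 = 3)), c(1, 1)),
               "grids")
  # close to the concatenation oracle when node distributions coincide
  set.seed(33)
  xs <- list(rnorm(4000), rnorm(4000))
  qs <- lapply(xs, function(x) quantile(x, c(.25, .5, .75), type = 7))
  pooled <- pool_quantiles(qs, c(4000, 4000))
  truth <- quantile(unlist(xs), c(.25, .5, .75), type = 7)
  expect_equal(unname(pooled), unname(truth), tolerance = 0.05)
})

test_that("federated statistics equal centralized ones without noise", {
  for (seed in c(2, 9)) {
    nodes <- as_nodes(generate_cohort(generator_params(seed = seed)))
    pooled <- dplyr::bind_rows(nodes)
    expect_equal(run_query(nodes, "creatinemia", "count")$value,
                 sum(!is.na(pooled$creatinemia)), tolerance = 1e-10)
    expect_equal(run_query(nodes, "creatinemia", "mean")$value,
                 mean(pooled$creatinemia, na.rm = TRUE), tolerance = 1e-10)
    expect_equal(run_query(nodes, "creatinemia", "sd")$value,
                 sd(pooled$creatinemia[!is.na(pooled$creatinemia)]),
                 tolerance = 1e-10)
    h <- run_query(nodes, "gender", "histogram")$value
    expect_equal(as.vector(h), as.vector(table(pooled$gender)))
  }
})

test_that("filters restrict the queried subset per node", {
  nodes <- fixture_nodes()
  res <- run_query(nodes, "creatinemia", "count", filter = period == "before")
  expect_equal(res$value, 75)
  res2 <- run_query(nodes, "creatinemia", "count", filter = period == "after")
  expect_equal(res2$value, 73)  # one missing creatinemia value
})

test_that("the fixture federation counts 118 progressed patients", {
  nodes <- lapply(fixture_nodes(), derive_outcome)
  res <- run_query(nodes, "patient_id", "count", filter = event == "progressed")
  expect_equal(res$value, 118)
})

test_that("single-node pooling is the identity", {
  nodes <- fixture_nodes()[1]
  local <- mean(nodes[[1]]$creatinemia, na.rm = TRUE)
  expect_equal(run_query(nodes, "creatinemia", "mean")$value, local)
})

test_that("extrema are refused without DP and bounded with it", {
  nodes <- fixture_nodes()
  expect_error(run_query(nodes, "creatinemia", "max"), "disclosive")
  s <- dp_stream(5)
  v <- run_query(nodes, "creatinemia", "max", dp = "local", epsilon = 5,
                 stream = s)$value
  expect_true(v >= 20 && v <= 300)
})

test_that("masked nodes are excluded with a flag; strict mode fails", {
  nodes <- fixture_nodes()
  nodes$tiny <- nodes[[1]][1:2, ]   # subset below min_subset_n after any filter
  res <- run_query(nodes, "creatinemia", "mean")
  expect_equal(res$masked, "tiny")
  full <- dplyr::bind_rows(nodes[names(nodes) != "tiny"])
  expect_equal(res$value, mean(full$creatinemia, na.rm = TRUE))
  expect_error(run_query(nodes, "creatinemia", "mean", strict = TRUE), "tiny")
  # all masked: hard error
  small <- lapply(nodes[1:2], function(df) df[1:2, ])
  expect_error(run_query(small, "creatinemia", "mean"), "masked")
})

test_that("schema mismatch across nodes is rejected", {
  nodes <- fixture_nodes()
  nodes[[2]] <- dplyr::select(nodes[[2]], -creatinemia)
  expect_error(run_query(nodes, "creatinemia", "mean"), "schema")
})

test_that("aggregate messages cannot carry per-record arrays", {
  msgs <- run_query(fixture_nodes(), "creatinemia", "sd")$messages
  for (m in msgs) {
    expect_true(all(lengths(m$payload) <= 32))
  }
  expect_error(
    fedstats:::aggregate_message("A", 100, "count",
                                 payload = list(x = as.numeric(1:100))),
    "per-record")
  # masked messages carry no payload at all
  mk <- fedstats:::aggregate_message("A", NA, "count", status = "masked")
  expect_null(mk$payload)
})

test_that("local DP noise variance scales with the number of nodes", {
  nodes <- lapply(1:3, function(i) {
    tibble::tibble(center = paste0("c", i), creatinemia = c(60, 65, 70, 75, 80))
  })
  names(nodes) <- paste0("c", 1:3)
  s <- dp_stream(2718)
  trials <- 1500
  loc <- vapply(1:trials, function(i) {
    run_query(nodes, "creatinemia", "sum", dp = "local", epsilon = 5,
              stream = s)$value
  }, numeric(1))
  cen <- vapply(1:trials, function(i) {
    run_query(nodes, "creatinemia", "sum", dp = "central", epsilon = 5,
              stream = s)$value
  }, numeric(1))
  expect_equal(var(loc) / var(cen), 3, tolerance = 0.35)
})

test_that("local DP charges every node; central DP charges once", {
  nodes <- fixture_nodes()
  s <- dp_stream(4)
  led <- new_ledger()
  run_query(nodes, "creatinemia", "mean", dp = "local", epsilon = 5,
            stream = s, ledger = led)
  tb <- ledger_entries(led)
  expect_setequal(unique(tb$node), names(nodes))
  expect_equal(sum(tb$epsilon), 5 * length(nodes))
  led2 <- new_ledger()
  run_query(nodes, "creatinemia", "mean", dp = "central", epsilon = 5,
            stream = s, ledger = led2)
  tb2 <- ledger_entries(led2)
  expect_equal(unique(tb2$node), "coordinator")
  expect_equal(sum(tb2$epsilon), 5)
})
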