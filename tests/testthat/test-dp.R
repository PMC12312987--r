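test_that("laplace mechanism is exact at zero sensitivity and seeded", {
  s <- dp_stream(10)
  expect_equal(laplace_release(42, epsilon = 1, sensitivity = 0, stream = s), 42)
  a <- laplace_release(0, 1, 1, dp_stream(77))
  b <- laplace_release(0, 1, 1, dp_stream(77))
  expect_identical(a, b)
  expect_false(laplace_release(0, 1, 1, dp_stream(78)) == a)
})

test_that("stream draws never disturb the session RNG state", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(laplace_release(0, 1, 1, dp_stream(5)))
  invisible(dp_quantile(1:20, c(0, 30), 0.5, 5, dp_stream(6)))
  expect_identical(runif(3), expected)
})

test_that("laplace noise calibration matches the analytic distribution", {
  s <- dp_stream(2024)
  draws <- vapply(1:20000, function(i) laplace_release(0, 5, 1, s), numeric(1))
  # P(|noise| > 1) = exp(-eps) for b = 1/eps
  expect_equal(mean(abs(draws) > 1), exp(-5), tolerance = 0.5)
  expect_equal(var(draws), 2 / 25, tolerance = 0.1)
  expect_equal(median(abs(draws)), log(2) / 5, tolerance = 0.1)
})

test_that("dp_count handles the empty case and composes additively", {
  led <- new_ledger()
  s <- dp_stream(1, noise_free = TRUE)
  expect_equal(dp_count(numeric(0), 5, s, led, "A"), 0)
  dp_count(1:10, 2, s, led, "A")
  dp_count(1:10, 3, s, led, "A")
  expect_equal(ledger_total(led, "A"), 10)
  tb <- ledger_entries(led)
  expect_equal(tb$cumulative, cumsum(tb$epsilon))
})

test_that("dp_count releases near the true count at the study budget", {
  s <- dp_stream(31)
  hits <- vapply(1:5000, function(i) {
    abs(dp_count(rep(1, 118), 5, s) - 118) <= 1
  }, logical(1))
  # P(|Lap(1/5)| <= 1) = 1 - exp(-5) ~ 0.9933
  expect_gt(mean(hits), 0.97)
})

test_that("dp_mean clamps, splits its budget, and degenerates exactly", {
  led <- new_ledger()
  s0 <- dp_stream(1, noise_free = TRUE)
  expect_equal(dp_mean(rep(7, 20), c(0, 10), 5, s0, led, "A"), 7)
  expect_equal(ledger_total(led, "A"), 5)  # half sum + half count
  # clamping bounds contributions
  expect_equal(dp_mean(c(-100, 100), c(0, 10), 5, s0), 5)
  expect_error(dp_mean(c(NA, NA), c(0, 10), 5, s0), "missing")
})

test_that("dp_mean error shrinks as n grows at fixed budget", {
  err_at <- function(n) {
    s <- dp_stream(n)
    x <- seq(0, 1, length.out = n)
    median(abs(vapply(1:300, function(i) {
      dp_mean(x, c(0, 1), 5, s) - 0.5
    }, numeric(1))))
  }
  expect_lt(err_at(1000), err_at(50))
})

test_that("dp_mean accuracy matches a brute-force mechanism oracle", {
  # oracle: simulate the same eps/2 + eps/2 split directly
  n <- 100; eps <- 5
  x <- seq(0, 1, length.out = n)
  rlap <- function(k, b) {
    u <- runif(k) - 0.5
    -b * sign(u) * log1p(-2 * abs(u))
  }
  set.seed(1234)
  oracle <- median(abs((sum(x) + rlap(1000, 1 / (eps / 2))) /
                         pmax(n + rlap(1000, 1 / (eps / 2)), 1) - mean(x)))
  s <- dp_stream(55)
  impl <- median(abs(vapply(1:1000, function(i) {
    dp_mean(x, c(0, 1), eps, s) - mean(x)
  }, numeric(1))))
  expect_equal(impl, oracle, tolerance = 0.2)
})

test_that("dp_variance floors at zero and degenerates to the sample variance", {
  s0 <- dp_stream(1, noise_free = TRUE)
  expect_equal(dp_variance(rep(3, 10), c(0, 10), 6, s0), 0)
  x <- c(1, 4, 9, 2, 7)
  expect_equal(dp_variance(x, c(0, 10), 6, s0), var(x))
  s <- dp_stream(9)
  draws <- vapply(1:2000, function(i) dp_variance(c(0, 0.01), c(0, 1), 0.5, s),
                  numeric(1))
  expect_true(all(draws >= 0))
})

test_that("dp_sd recovers a unit standard deviation at the t-test budget", {
  set.seed(42)
  x <- rnorm(1000)
  s <- dp_stream(7)
  sds <- vapply(1:200, function(i) dp_sd(x, c(-5, 5), 60, s), numeric(1))
  expect_gt(mean(sds >= 0.85 & sds <= 1.15), 0.95)
})

test_that("dp_extremum stays within bounds and has the expected error", {
  s0 <- dp_stream(1, noise_free = TRUE)
  expect_equal(dp_extremum(rep(9, 5), c(0, 9), 5, s0, which = "max"), 9)
  s <- dp_stream(13)
  rel <- vapply(1:1000, function(i) {
    dp_extremum(c(100, 900), c(0, 1500), 5, s, which = "max")
  }, numeric(1))
  expect_true(all(rel >= 0 & rel <= 1500))
  # median absolute error ~ b log 2 = 1500 log(2) / 5 ~ 208 days
  expect_equal(median(abs(rel - 900)), 1500 * log(2) / 5, tolerance = 0.15)
})

test_that("dp_quantile concentrates around the true quantile", {
  s <- dp_stream(3)
  expect_equal(dp_quantile(5, c(0, 10), 0.3, 5, s), 5, tolerance = 5)
  med <- vapply(1:300, function(i) {
    dp_quantile(1:99, c(0, 100), 0.5, 60, s)
  }, numeric(1))
  expect_true(all(med >= 0 & med <= 100))
  expect_gt(mean(med >= 40 & med <= 60), 0.99)
  # noise-free mode returns the exact sample quantile
  s0 <- dp_stream(1, noise_free = TRUE)
  expect_equal(dp_quantile(1:99, c(0, 100), 0.5, 60, s0), 50)
})

test_that("dp_histogram releases integer bins under parallel composition", {
  led <- new_ledger()
  s0 <- dp_stream(1, noise_free = TRUE)
  cats <- c("a", "b", "c")
  expect_equal(unname(dp_histogram(character(0), cats, 5, s0, led, "A")),
               c(0L, 0L, 0L))
  expect_equal(ledger_total(led, "A"), 5)  # one table = one charge
  expect_error(dp_histogram(c("a", "z"), cats, 5, s0), "z")
  s <- dp_stream(17)
  x <- rep(c("a", "b", "c", "d"), c(46, 6, 7, 16))
  hits <- vapply(1:3000, function(i) {
    all(abs(dp_histogram(x, c("a", "b", "c", "d"), 5, s) -
              c(46, 6, 7, 16)) <= 1)
  }, logical(1))
  # per-bin P(|Lap(1/5)| <= 1.5 after rounding) >= 1 - exp(-5); 4 bins
  expect_gt(mean(hits), 0.97)
  expect_true(all(dp_histogram(x, c("a", "b", "c", "d"), 0.2, s) >= 0))
})

test_that("count release satisfies the epsilon-indistinguishability bound", {
  eps <- 1
  s <- dp_stream(101)
  d_n <- vapply(1:40000, function(i) laplace_release(50, eps, 1, s), numeric(1))
  d_n1 <- vapply(1:40000, function(i) laplace_release(51, eps, 1, s), numeric(1))
  br <- seq(44, 57, by = 1)
  h_n <- hist(d_n[d_n >= 44 & d_n <= 57], breaks = br, plot = FALSE)$counts
  h_n1 <- hist(d_n1[d_n1 >= 44 & d_n1 <= 57], breaks = br, plot = FALSE)$counts
  keep <- h_n > 200 & h_n1 > 200
  ratio <- h_n[keep] / h_n1[keep]
  # density ratio bounded by exp(eps) everywhere (with sampling slack)
  expect_true(all(ratio <= exp(eps) * 1.25 & ratio >= exp(-eps) / 1.25))
})

test_that("post-processing never touches the ledger", {
  led <- new_ledger()
  s <- dp_stream(21)
  dp_histogram(rep("a", 10), c("a", "b"), 5, s, led, "A")   # rounds internally
  dp_extremum(1:10, c(0, 20), 5, s, which = "max", ledger = led, node = "A")
  expect_equal(ledger_total(led, "A"), 10)
  expect_equal(nrow(ledger_entries(led)), 2)
})

test_that("every mechanism in noise-free mode equals its exact counterpart", {
  s0 <- dp_stream(99, noise_free = TRUE)
  x <- c(3.2, 8.1, 5.5, 9.9, 1.1, 7.7)
  b <- c(0, 10)
  expect_equal(dp_count(x, 5, s0), 6)
  expect_equal(dp_mean(x, b, 5, s0), mean(x))
  expect_equal(dp_variance(x, b, 5, s0), var(x))
  expect_equal(dp_sd(x, b, 5, s0), sd(x))
  expect_equal(dp_extremum(x, b, 5, s0, "min"), min(x))
  expect_equal(dp_extremum(x, b, 5, s0, "max"), max(x))
  expect_equal(dp_quantile(x, b, 0.5, 5, s0),
               unname(quantile(x, 0.5, type = 7)))
  expect_equal(unname(dp_histogram(c("a", "a", "b"), c("a", "b"), 5, s0)),
               c(2L, 1L))
})

test_that("ledger exports one JSON line per release", {
  led <- new_ledger()
  s <- dp_stream(1)
  dp_count(1:5, 2, s, led, "A")
  dp_mean(1:5, c(0, 10), 4, s, led, "B")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_ledger_jsonl(led, path)
  lines <- readLines(path)
  expect_length(lines, 3)  # count + mean.sum + mean.count
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed$epsilon, 2)
  expect_equal(parsed$node, "A")
})
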