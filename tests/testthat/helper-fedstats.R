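# Shared fixtures and independent oracles for the test suite.

# one small 3-node federation built from the deterministic fixture
fixture_nodes <- function(seed = 1L) {
  as_nodes(build_fixture(seed = seed))
}

# minimal hand-built cohort rows for targeted validation tests
toy_cohort <- function(n = 6, center = "A") {
  tibble::tibble(
    patient_id = sprintf("%s-%02d", center, seq_len(n)),
    center = center,
    inclusion_date = as.Date("2019-06-01") + seq_len(n),
    gender = rep(c("Female", "Male"), length.out = n),
    age_class = rep(c("<55", "55-65", ">65"), length.out = n),
    bmi_class = rep(c("<18.5", "18.5-25", ">25"), length.out = n),
    treatment_category = rep(c("Chemotherapy", "Immunotherapy"), length.out = n),
    creatinemia = 50 + 5 * (seq_len(n) - 1),
    firstline_duration_days = 10 + 20 * (seq_len(n) - 1),
    secondline_start_day = NA_real_,
    death_day = NA_real_,
    transfer_day = NA_real_)
}

# independent Fisher oracle: exhaustive enumeration of all tables with the
# observed margins, probability-mass two-sided criterion
fisher_oracle <- function(tab) {
  tab <- as.matrix(tab)
  r <- rowSums(tab); c_ <- colSums(tab)
  nr <- nrow(tab); nc <- ncol(tab)
  log_p <- function(m) {
    # multivariate hypergeometric probability of a table given its margins
    sum(lfactorial(r)) + sum(lfactorial(c_)) - lfactorial(sum(m)) -
      sum(lfactorial(m))
  }
  tables <- list()
  fill <- function(m, i, j) {
    if (i == nr && j == nc) {
      m[i, j] <- r[i] - sum(m[i, -nc])
      if (m[i, j] == c_[nc] - sum(m[-nr, nc]) && m[i, j] >= 0) {
        tables[[length(tables) + 1L]] <<- m
      }
      return(invisible())
    }
    if (j == nc) {          # last column of a non-final row is determined
      m[i, j] <- r[i] - sum(m[i, -nc])
      if (m[i, j] < 0) return(invisible())
      fill(m, i + 1L, 1L)
      return(invisible())
    }
    remaining_col <- c_[j] - sum(m[seq_len(i - 1L), j])
    for (v in 0:min(r[i] - sum(m[i, seq_len(j - 1L)]), remaining_col)) {
      m[i, j] <- v
      fill(m, i, j + 1L)
    }
  }
  fill(matrix(0L, nr, nc), 1L, 1L)
  lp <- vapply(tables, log_p, numeric(1))
  lp_obs <- log_p(tab)
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# pooled-data t-test oracle: build raw samples with the requested summary
# statistics and run stats::t.test on them
t_oracle <- function(n1, m1, s1, n2, m2, s2) {
  mk <- function(n, m, s) {
    z <- stats::rnorm(n)
    m + (z - mean(z)) * (s / stats::sd(z))
  }
  x <- mk(n1, m1, s1); y <- mk(n2, m2, s2)
  stats::t.test(x, y, var.equal = TRUE)
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
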