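# Brute-force oracles computed from first principles, kept independent of
# the implementation's code paths.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
midrank_oracle <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, 0)
}

test_that("spearman_r equals Pearson on mid-ranks (oracle identity)", {
  expect_equal(spearman_r(1:8, (1:8)^3), 1)
  expect_equal(spearman_r(1:8, rev(1:8)), -1)
  set.seed(2)
  for (i in 1:5) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    expect_equal(spearman_r(a, b),
                 pearson_oracle(midrank_oracle(a), midrank_oracle(b)),
                 tolerance = 1e-12)
  }
  # ties handled by average ranks
  a <- c(1, 1, 2, 3, 3, 4); b <- c(2, 1, 4, 4, 5, 7)
  expect_equal(spearman_r(a, b),
               pearson_oracle(midrank_oracle(a), midrank_oracle(b)),
               tolerance = 1e-12)
  expect_warning(r <- spearman_r(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("spearman_r is invariant under strictly monotone transforms", {
  set.seed(3)
  a <- stats::rlnorm(15); b <- stats::rnorm(15)
  r0 <- spearman_r(a, b)
  expect_equal(spearman_r(log(a), b), r0)
  expect_equal(spearman_r(a, exp(b / 2)), r0)
  expect_equal(spearman_r(rank(a), b), r0)
})

test_that("bland_altman matches the direct formula and mirrors on swap", {
  a <- c(1.2, 0.9, 1.5, 1.1, 1.3); b <- c(1.0, 1.0, 1.4, 1.2, 1.1)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
               tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * ba$sd_diff, tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * ba$sd_diff, tolerance = 1e-12)
  sw <- bland_altman(b, a)
  expect_equal(sw$mean_diff, -ba$mean_diff)
  expect_equal(sw$sd_diff, ba$sd_diff)

  same <- bland_altman(a, a)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  off <- bland_altman(a, a - 0.1)
  expect_equal(off$mean_diff, 0.1)
  expect_equal(off$sd_diff, 0)
})

test_that("sd_percent_diff matches its formula and scales out", {
  a <- c(1.0, 1.2, 0.8, 1.1, 0.9, 1.05); b <- c(1.1, 1.0, 0.9, 1.0, 1.0, 1.0)
  pd <- 100 * (a - b) / ((a + b) / 2)
  expect_equal(sd_percent_diff(a, b), stats::sd(pd), tolerance = 1e-12)
  expect_equal(sd_percent_diff(a, a), 0)
  expect_equal(sd_percent_diff(1.1 * a, a), 0, tolerance = 1e-12)
  # invariant under common positive rescaling
  expect_equal(sd_percent_diff(5 * a, 5 * b), sd_percent_diff(a, b),
               tolerance = 1e-12)
  expect_warning(sd_percent_diff(c(a, 1), c(b, -1)), "excluded")
})

test_that("independent Fisher-z test: closed form and symmetry", {
  eq <- fisher_z_independent(0.8, 30, 0.8, 40)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  fz <- fisher_z_independent(0.954, 57, 0.942, 50)
  z_oracle <- (atanh(0.954) - atanh(0.942)) / sqrt(1 / 54 + 1 / 47)
  expect_equal(fz$z, z_oracle, tolerance = 1e-12)
  sw <- fisher_z_independent(0.942, 50, 0.954, 57)
  expect_equal(sw$z, -fz$z)
  expect_equal(sw$p, fz$p)
  expect_error(fisher_z_independent(1, 30, 0.5, 30), "\\|r\\| < 1")
  expect_error(fisher_z_independent(0.5, 3, 0.5, 30), "exceed 3")
})

test_that("dependent Fisher-z test: symmetry, r12 monotonicity, r12=0 limit", {
  expect_equal(fisher_z_dependent(0.9, 0.9, 0.5, 50)$z, 0)
  expect_equal(fisher_z_dependent(0.9, 0.9, 0.5, 50)$p, 1)
  ps <- vapply(c(0, 0.3, 0.6, 0.9),
               function(r12) fisher_z_dependent(0.92, 0.85, r12, 100)$p, 0)
  expect_true(all(diff(ps) < 0))
  # r12 = 0 reduces to the independent test with equal n
  dep0 <- fisher_z_dependent(0.92, 0.85, 0, 100)
  ind <- fisher_z_independent(0.92, 100, 0.85, 100)
  expect_equal(dep0$z, ind$z, tolerance = 1e-12)
  # two uncorrelated measures cannot both correlate 0.9 with each other's pair
  expect_error(fisher_z_dependent(0, 0, 0.9, 50), "triple")
})

test_that("F-test and paired t match textbook formulas", {
  expect_equal(f_test_sd(0.5, 20, 0.5, 25)$F, 1)
  ft <- f_test_sd(0.8, 12, 0.5, 15)
  expect_equal(ft$F, 0.64 / 0.25, tolerance = 1e-12)
  p_oracle <- 2 * min(stats::pf(2.56, 11, 14), 1 - stats::pf(2.56, 11, 14))
  expect_equal(ft$p, p_oracle, tolerance = 1e-10)

  a <- c(2.1, 1.9, 2.4, 2.0, 2.2); b <- c(2.0, 2.0, 2.1, 1.9, 2.05)
  tt <- paired_t(a, b)
  d <- a - b
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(tt$t, t_oracle, tolerance = 1e-12)
  expect_equal(tt$p, 2 * stats::pt(-abs(t_oracle), length(d) - 1),
               tolerance = 1e-12)
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
})

test_that("agreement_summary combines the battery coherently", {
  set.seed(8)
  a <- stats::rlnorm(30); b <- a * stats::rlnorm(30, 0, 0.05)
  s <- agreement_summary(a, b)
  expect_equal(s$r_spearman, spearman_r(a, b))
  expect_equal(s$sd_diff, bland_altman(a, b)$sd_diff)
  expect_equal(s$sd_percent_diff, sd_percent_diff(a, b))
  expect_true(is.finite(s$shapiro_p))
})
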