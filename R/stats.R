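# Repeatability-statistics battery for paired measurement series.

check_paired <- function(a, b, n_min = 3) {
  if (length(a) != length(b)) abort_input("`a` and `b` must have equal length")
  if (length(a) < n_min) abort_input("need at least %d pairs", n_min)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    abort_input("values must be finite")
  invisible(NULL)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks).
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return A single correlation in `[-1, 1]`; `NA` with a warning when
#'   either vector is constant (ranks undefined up to ties).
#' @export
spearman_r <- function(a, b) {
  check_paired(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(a), rank(b))
}

#' Bland-Altman agreement summary
#'
#' Differences `d = a - b`: mean difference, sample SD (n - 1 denominator)
#' and 95% limits of agreement `mean +/- 1.96 SD`.
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return One-row tibble: `n`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`.
#' @export
bland_altman <- function(a, b) {
  check_paired(a, b)
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  tibble::tibble(n = length(d), mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Standard deviation of the percentage difference
#'
#' Precision metric for paired measurements: the sample SD of
#' `100 * (a_i - b_i) / ((a_i + b_i) / 2)`. Pairs with non-positive mean are
#' excluded (with a warning) since the percentage is undefined there.
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return The SD in percent (scalar).
#' @export
sd_percent_diff <- function(a, b) {
  check_paired(a, b)
  pm <- (a + b) / 2
  ok <- pm > 0
  if (!all(ok)) warning(sprintf("%d pair(s) with non-positive mean excluded",
                                sum(!ok)))
  if (sum(ok) < 3) abort_input("fewer than 3 usable pairs")
  stats::sd(100 * (a[ok] - b[ok]) / pm[ok])
}

#' Compare two independent correlation coefficients (Fisher z)
#'
#' Two-sided z-test for correlations from independent groups:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Group sizes (> 3).
#' @return One-row tibble: `z`, `p` (two-sided normal tail).
#' @export
fisher_z_independent <- function(r1, n1, r2, n2) {
  for (r in c(r1, r2)) if (!is.finite(r) || abs(r) >= 1)
    abort_input("correlations must satisfy |r| < 1")
  for (n in c(n1, n2)) if (n <= 3) abort_input("group sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two dependent correlation coefficients (paired-samples z)
#'
#' Steiger-style z-test for two correlations measured on the same subjects
#' and sharing no variable, given the correlation `r12` between the two
#' measures. The covariance of the Fisher-transformed correlations is
#' approximated by `r12^2`, giving
#' `z = (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12^2)))`;
#' at `r12 = 0` this reduces to the independent-samples test with equal
#' group sizes, and the test grows more sensitive as `r12` increases.
#'
#' @param r1,r2 Correlations to compare (`|r| < 1`).
#' @param r12 Correlation between the two underlying measures.
#' @param n Number of paired subjects (> 3).
#' @return One-row tibble: `z`, `p`.
#' @export
fisher_z_dependent <- function(r1, r2, r12, n) {
  for (r in c(r1, r2, r12)) if (!is.finite(r) || abs(r) >= 1)
    abort_input("correlations must satisfy |r| < 1")
  if (n <= 3) abort_input("`n` must exceed 3")
  # feasibility over the four underlying variables (a1, a2, b1, b2), with
  # r12 standing for the four cross-measure correlations: the implied 4x4
  # correlation matrix must be positive semi-definite
  M <- matrix(c(1, r1, r12, r12,
                r1, 1, r12, r12,
                r12, r12, 1, r2,
                r12, r12, r2, 1), 4, 4)
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    abort_input("(r1, r2, r12) is not a valid correlation triple")
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12^2)))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sided F-test comparing two standard deviations
#'
#' @param sd1,sd2 Positive sample standard deviations.
#' @param n1,n2 Sample sizes (>= 2).
#' @return One-row tibble: `F` (`sd1^2 / sd2^2`), `df1`, `df2`, `p`.
#' @export
f_test_sd <- function(sd1, n1, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) abort_input("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) abort_input("sample sizes must be at least 2")
  F <- sd1^2 / sd2^2
  pl <- stats::pf(F, n1 - 1, n2 - 1)
  tibble::tibble(F = F, df1 = n1 - 1, df2 = n2 - 1,
                 p = 2 * min(pl, 1 - pl))
}

#' Paired-samples t-test on the differences
#'
#' Thin wrapper over [stats::t.test()] with a zero-variance guard: when all
#' differences are identical the statistic is undefined, and the result is
#' flagged (`t = 0`, `p = 1` for identically zero differences).
#'
#' @param a,b Numeric vectors of equal length (>= 2... 3 enforced).
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  check_paired(a, b)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                          df = length(d) - 1,
                          p = if (mean(d) == 0) 1 else 0,
                          mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Full agreement summary for one paired series
#'
#' Combines Spearman correlation, Bland-Altman agreement, the SD of
#' percentage difference and a Shapiro-Wilk normality screen of the
#' differences (the screen annotates which cells warrant Bland-Altman
#' interpretation; it does not gate any computation).
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return One-row tibble with `n`, `r_spearman`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `sd_percent_diff`, `shapiro_p`, `normal_diff`.
#' @export
agreement_summary <- function(a, b) {
  check_paired(a, b)
  ba <- bland_altman(a, b)
  r <- suppressWarnings(spearman_r(a, b))
  spd <- suppressWarnings(sd_percent_diff(a, b))
  sh <- if (stats::sd(a - b) > 0 && length(a) >= 3 && length(a) <= 5000)
    tryCatch(stats::shapiro.test(a - b)$p.value, error = function(e) NA_real_)
  else NA_real_
  dplyr::mutate(ba, r_spearman = r, sd_percent_diff = spd,
                shapiro_p = sh, normal_diff = !is.na(sh) & sh > 0.05,
                .after = "n")
}
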