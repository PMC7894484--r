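test_that("normality screen passes normal samples at the advertised rate", {
  set.seed(1)
  expect_true(ks_normality(rnorm(500))$pass)

  passes <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(rnorm(500))$pass
  }, logical(1))
  band <- 3 * sqrt(0.95 * 0.05 / 100)
  expect_gt(mean(passes), 0.95 - band)

  # gross non-normality is rejected
  set.seed(4)
  mass2 <- sample(c(0, 10), 500, replace = TRUE)
  expect_false(ks_normality(mass2)$pass)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "n >= 3")
})

test_that("small-sample normality screen is deterministic and sane", {
  a <- ks_normality(c(1.2, 2.4, 3.1))
  b <- ks_normality(c(1.2, 2.4, 3.1))
  expect_identical(a$p_value, b$p_value)
  expect_true(a$p_value >= 0 && a$p_value <= 1)
  # asymptotic variant is available and anti-conservative relative to it
  naive <- ks_normality(c(1.2, 2.4, 3.1, 2.2), method = "asymptotic")
  expect_s3_class(naive, "ks_normality")
})

test_that("variance F-test is two-tailed with the larger variance on top", {
  g <- rnorm(20)
  expect_true(f_test_variances(g, g + 1)$equal)

  set.seed(6)
  a <- rnorm(20, sd = 1); b <- rnorm(20, sd = 10)
  ft <- f_test_variances(a, b)
  expect_false(ft$equal)
  f <- max(var(a), var(b)) / min(var(a), var(b))
  p_oracle <- 2 * min(pf(f, 19, 19), pf(f, 19, 19, lower.tail = FALSE))
  expect_equal(ft$p_value, p_oracle, tolerance = 1e-12)

  # printed panel s.e.m.s 3.2 vs 6.3 at n = 3: ratio ~3.9 is far below the
  # two-tailed F(2,2) critical value (~39), so variances count as equal
  ft2 <- f_test_variances(group_summary(mean = 44.5, sem = 3.2, n = 3),
                          group_summary(mean = 69.5, sem = 6.3, n = 3))
  expect_true(ft2$equal)
  expect_error(f_test_variances(rep(1, 3), rnorm(3)), "zero variance")
})

test_that("branching comparison picks Student or Welch and handles degenerate groups", {
  x <- c(1.1, 2.3, 2.9, 4.2)
  self <- suppressWarnings(compare_groups(x, x))
  expect_equal(self$t, 0, tolerance = 1e-12)
  expect_equal(self$p_two_tailed, 1, tolerance = 1e-12)

  both_const <- compare_groups(c(0, 0, 0), c(0, 0, 0))
  expect_equal(both_const$p_two_tailed, 1)
  expect_equal(compare_groups(c(0, 0, 0), c(1, 1, 1))$p_two_tailed, 0)

  set.seed(2)
  a <- rnorm(10); b <- rnorm(10, sd = 12)
  cmp <- suppressWarnings(compare_groups(a, b))
  expect_equal(cmp$test_used, "welch")
  expect_false(cmp$variances_equal)
})

test_that("power of the comparison matches the noncentral-t oracle on a printed-panel contrast", {
  # groups shaped like the random-coil panel: n = 19, means 22.4 vs 24.9,
  # sds chosen so the s.e.m.s are 0.5 and 0.4
  n <- 19; m1 <- 22.4; m2 <- 24.9
  sd1 <- 0.5 * sqrt(n); sd2 <- 0.4 * sqrt(n)
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    suppressWarnings(
      compare_groups(rnorm(n, m1, sd1), rnorm(n, m2, sd2))$p_two_tailed) < 0.005
  }, logical(1))
  ncp <- (m2 - m1) / sqrt(sd1^2 / n + sd2^2 / n)
  df <- 2 * n - 2
  crit <- qt(1 - 0.005 / 2, df)
  power <- 1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
  band <- 3 * sqrt(power * (1 - power) / 100)
  expect_gt(mean(hits), power - band)
  expect_lt(mean(hits), power + band)
})

test_that("summary-statistics comparison reproduces closed forms and raw-data results", {
  # printed residual-pigment contrasts at n = 3
  up <- compare_from_summary(44.5, 3.2, 3, 61.4, 4.0, 3)
  expect_lt(up$p_two_tailed, 0.05)
  expect_equal(up$test_used, "student")
  ns <- compare_from_summary(44.5, 3.2, 3, 49.1, 4.9, 3)
  expect_gt(ns$p_two_tailed, 0.05)
  same <- compare_from_summary(44.5, 3.2, 3, 44.5, 3.2, 3)
  expect_equal(same$p_two_tailed, 1, tolerance = 1e-12)
  expect_error(compare_from_summary(1, 0, 3, 2, 1, 3), "positive")

  # oracle: rebuild raw vectors with exactly the summary moments and run t.test
  vec_with <- function(m, sem, n) {
    base <- scale(seq_len(n))[, 1]
    m + base * sem * sqrt(n)
  }
  for (case in list(c(44.5, 3.2, 61.4, 4.0), c(44.5, 3.2, 49.1, 4.9))) {
    a <- vec_with(case[1], case[2], 3); b <- vec_with(case[3], case[4], 3)
    ours <- compare_from_summary(case[1], case[2], 3, case[3], case[4], 3)
    ref <- t.test(a, b, var.equal = ours$variances_equal)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Student branch equals the textbook pooled form; Welch df is bounded", {
  # equal n, equal sd: pooled closed form to machine precision
  m1 <- 5; m2 <- 6.2; sem <- 0.7; n <- 8
  cmp <- compare_from_summary(m1, sem, n, m2, sem, n)
  t_closed <- (m1 - m2) / (sem * sqrt(2))
  expect_equal(cmp$t, t_closed, tolerance = 1e-12)
  expect_equal(cmp$df, 2 * n - 2)

  # Welch df never exceeds n1 + n2 - 2; equal variances make Welch = Student
  set.seed(10)
  for (rep in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    v1 <- s1^2; v2 <- s2^2
    df_w <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    expect_lte(df_w, n1 + n2 - 2 + 1e-9)
  }
  welch_t <- (m1 - m2) / sqrt(sem^2 + sem^2)
  expect_equal(welch_t, t_closed, tolerance = 1e-9)
})
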