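# Branching significance protocol: Kolmogorov-Smirnov normality screen,
# F-test on variances, then Student's (equal variances) or Welch's (unequal)
# two-tailed t-test.  A summary-statistics variant handles printed
# mean +/- s.e.m. tables.

#' Group summary statistics
#'
#' @param values raw observations (optional when `mean`, `sem`, `n` given).
#' @param mean,sem,n summary statistics; recomputed from `values` when those
#'   are supplied.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(values = NULL, mean = NULL, sem = NULL, n = NULL) {
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) < 2L) stop("need n >= 2 observations")
    m <- base::mean(values)
    s <- stats::sd(values) / sqrt(length(values))
    if (!is.null(mean) && abs(mean - m) > 1e-9) {
      stop("stored mean disagrees with values")
    }
    if (!is.null(sem) && abs(sem - s) > 1e-9) stop("stored sem disagrees with values")
    mean <- m; sem <- s; n <- length(values)
  } else {
    if (is.null(mean) || is.null(sem) || is.null(n)) {
      stop("give either values or mean, sem and n")
    }
    if (n < 2L) stop("need n >= 2")
    if (sem < 0) stop("sem must be non-negative")
  }
  structure(list(mean = mean, sem = sem, n = as.integer(n), values = values),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary: %.4g +/- %.4g (s.e.m., n = %d)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

.as_group <- function(x) {
  if (inherits(x, "group_summary")) x else group_summary(values = x)
}

# Lilliefors test statistic: KS distance between the empirical cdf and a
# normal with the sample mean and sd.
.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

# Null distributions of the Lilliefors statistic for tiny n, where the
# Dallal-Wilkinson approximation (nortest) is unavailable.  Computed once
# per n by vectorised Monte Carlo under a fixed internal stream (RNG state
# restored), then cached for the session.
.lillie_null_cache <- new.env(parent = emptyenv())

.lilliefors_null <- function(n, reps = 20000L) {
  key <- paste0("n", n)
  if (!is.null(.lillie_null_cache[[key]])) return(.lillie_null_cache[[key]])
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(902131L)
  X <- matrix(stats::rnorm(reps * n), nrow = reps)
  Z <- (X - rowMeans(X)) / sqrt(apply(X, 1, stats::var))
  Z <- t(apply(Z, 1, sort))
  P <- stats::pnorm(Z)
  I <- matrix(seq_len(n), nrow = reps, ncol = n, byrow = TRUE)
  D <- pmax(apply(I / n - P, 1, max), apply(P - (I - 1) / n, 1, max))
  .lillie_null_cache[[key]] <- sort(D)
  .lillie_null_cache[[key]]
}

#' Normality screen by the Kolmogorov-Smirnov (Lilliefors) test
#'
#' One-sample KS test against a normal distribution with mean and sd
#' estimated from the sample.  Because the parameters are estimated, the
#' default uses Lilliefors-corrected critical values (the naive asymptotic
#' KS test is anti-conservative in this setting and is available as
#' `method = "asymptotic"`).  For n < 5 the Lilliefors null distribution is
#' obtained by cached Monte Carlo, so the result is deterministic.
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @param alpha significance level (default 0.05); the screen passes when
#'   p >= alpha.
#' @param method `"lilliefors"` (default) or `"asymptotic"`.
#' @return An object of class `ks_normality`: `pass`, `statistic`,
#'   `p_value`, `method`, `n`.
#' @export
ks_normality <- function(values, alpha = 0.05, method = c("lilliefors", "asymptotic")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(values) == 0) stop("constant input: normality test is degenerate")
  if (method == "asymptotic") {
    ht <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
    D <- unname(ht$statistic); p <- ht$p.value
  } else if (n >= 5L) {
    ht <- nortest::lillie.test(values)
    D <- unname(ht$statistic); p <- ht$p.value
  } else {
    D <- .lilliefors_stat(values)
    null <- .lilliefors_null(n)
    p <- (sum(null >= D) + 1) / (length(null) + 1)
  }
  structure(list(pass = p >= alpha, statistic = D, p_value = p,
                 method = method, n = n, alpha = alpha),
            class = "ks_normality")
}

#' @export
print.ks_normality <- function(x, ...) {
  cat(sprintf("ks_normality (%s): D = %.4f, p = %.4g, n = %d -> %s\n",
              x$method, x$statistic, x$p_value, x$n,
              if (x$pass) "consistent with normal" else "normality rejected"))
  invisible(x)
}

#' Two-tailed F-test for equality of variances
#'
#' The statistic is the larger over the smaller sample variance; the
#' two-tailed p-value is `2 * min(P(F <= f), P(F >= f))`, capped at 1.
#' Variances are taken as equal when p >= alpha.
#'
#' @param g1,g2 numeric vectors or [group_summary] objects (sd is
#'   reconstructed from s.e.m. as `sem * sqrt(n)` when only summaries are
#'   available).
#' @param alpha significance level.
#' @return An object of class `f_test`: `equal`, `statistic`, `df`,
#'   `p_value`.
#' @export
f_test_variances <- function(g1, g2, alpha = 0.05) {
  g1 <- .as_group(g1); g2 <- .as_group(g2)
  s1 <- g1$sem * sqrt(g1$n); s2 <- g2$sem * sqrt(g2$n)
  if (s1 <= 0 || s2 <= 0) stop("zero variance in a group")
  if (s1^2 >= s2^2) {
    f <- s1^2 / s2^2; df <- c(g1$n - 1L, g2$n - 1L)
  } else {
    f <- s2^2 / s1^2; df <- c(g2$n - 1L, g1$n - 1L)
  }
  p <- min(1, 2 * min(stats::pf(f, df[1], df[2]),
                      stats::pf(f, df[1], df[2], lower.tail = FALSE)))
  structure(list(equal = p >= alpha, statistic = f, df = df, p_value = p,
                 alpha = alpha),
            class = "f_test")
}

#' @export
print.f_test <- function(x, ...) {
  cat(sprintf("f_test: F(%d,%d) = %.3f, p = %.4g -> variances %s\n",
              x$df[1], x$df[2], x$statistic, x$p_value,
              if (x$equal) "equal" else "unequal"))
  invisible(x)
}

.stat_comparison <- function(normality_pass, variances_equal, test_used,
                             t, df, p, alpha) {
  structure(list(normality_pass = normality_pass,
                 variances_equal = variances_equal,
                 test_used = test_used, t = t, df = df,
                 p_two_tailed = min(1, max(0, p)), alpha = alpha),
            class = "stat_comparison")
}

#' Branching two-group comparison on raw values
#'
#' Screens each group for normality ([ks_normality()]), tests variance
#' equality ([f_test_variances()]), then applies the two-tailed Student's
#' t-test (pooled variance) when variances are equal and Welch's t-test
#' otherwise.  A normality failure is recorded as a flag (with a warning),
#' not a hard stop.
#'
#' @param g1,g2 numeric vectors (n >= 2 each) or [group_summary] objects
#'   carrying raw values.
#' @param alpha significance level for every stage.
#' @return An object of class `stat_comparison`: `normality_pass` (pair of
#'   logicals), `variances_equal`, `test_used` (`"student"` or `"welch"`),
#'   `t`, `df`, `p_two_tailed`.
#' @export
compare_groups <- function(g1, g2, alpha = 0.05) {
  g1 <- .as_group(g1); g2 <- .as_group(g2)
  if (is.null(g1$values) || is.null(g2$values)) {
    stop("compare_groups needs raw values; use compare_from_summary otherwise")
  }
  s1 <- stats::sd(g1$values); s2 <- stats::sd(g2$values)
  if (s1 == 0 && s2 == 0) {
    # both groups constant: equal means are indistinguishable, unequal ones
    # trivially different
    same <- g1$mean == g2$mean
    return(.stat_comparison(c(NA, NA), TRUE, "student",
                            if (same) 0 else Inf, g1$n + g2$n - 2,
                            if (same) 1 else 0, alpha))
  }
  if (s1 == 0 || s2 == 0) {
    warning("one group is constant; normality and variance tests skipped, ",
            "Welch's t-test applied")
    ht <- stats::t.test(g1$values, g2$values, var.equal = FALSE)
    return(.stat_comparison(c(NA, NA), FALSE, "welch",
                            unname(ht$statistic), unname(ht$parameter),
                            ht$p.value, alpha))
  }
  norm1 <- ks_normality(g1$values, alpha)$pass
  norm2 <- ks_normality(g2$values, alpha)$pass
  if (!norm1 || !norm2) {
    warning("normality screen failed for at least one group; ",
            "t-test applied anyway (flagged)")
  }
  ft <- f_test_variances(g1, g2, alpha)
  ht <- stats::t.test(g1$values, g2$values, var.equal = ft$equal)
  .stat_comparison(c(norm1, norm2), ft$equal,
                   if (ft$equal) "student" else "welch",
                   unname(ht$statistic), unname(ht$parameter), ht$p.value, alpha)
}

#' Branching two-group comparison from printed summaries
#'
#' Applies the same F-test then Student/Welch branch as [compare_groups()]
#' starting from mean, s.e.m. and n of each group (sd reconstructed as
#' `sem * sqrt(n)`).  The normality screen cannot be run without raw values
#' and is recorded as untested (`NA`).
#'
#' @param m1,sem1,n1 mean, s.e.m. and size of group 1.
#' @param m2,sem2,n2 mean, s.e.m. and size of group 2.
#' @param alpha significance level.
#' @return A `stat_comparison` (see [compare_groups()]).
#' @export
compare_from_summary <- function(m1, sem1, n1, m2, sem2, n2, alpha = 0.05) {
  if (sem1 <= 0 || sem2 <= 0) stop("s.e.m. values must be positive")
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 in both groups")
  g1 <- group_summary(mean = m1, sem = sem1, n = n1)
  g2 <- group_summary(mean = m2, sem = sem2, n = n2)
  ft <- f_test_variances(g1, g2, alpha)
  v1 <- (sem1 * sqrt(n1))^2; v2 <- (sem2 * sqrt(n2))^2
  if (ft$equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  .stat_comparison(c(NA, NA), ft$equal,
                   if (ft$equal) "student" else "welch", t, df, p, alpha)
}

#' @export
print.stat_comparison <- function(x, ...) {
  norm <- if (all(is.na(x$normality_pass))) "untested"
          else paste(ifelse(x$normality_pass, "pass", "FAIL"), collapse = "/")
  cat(sprintf(
    "stat_comparison: %s t = %.3f, df = %.2f, two-tailed p = %.4g\n",
    x$test_used, x$t, x$df, x$p_two_tailed))
  cat(sprintf("  normality: %s; variances %s (alpha = %g)\n",
              norm, if (x$variances_equal) "equal" else "unequal", x$alpha))
  invisible(x)
}
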