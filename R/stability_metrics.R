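# Experimental stability analytics: residual pigment, single-exponential
# decoloration kinetics, DSC thermogram processing with melting-temperature
# extraction, and the stabilization classification rule.

#' Residual pigment after heat incubation
#'
#' Ratio of the absorbance maximum (530 nm) after a heat incubation to that
#' before, in percent.  Higher values indicate thermo-stabilization.
#'
#' @param abs_before absorbance before incubation (> 0).
#' @param abs_after absorbance after incubation (>= 0).
#' @return Residual pigment in percent.
#' @export
residual_pigment <- function(abs_before, abs_after) {
  if (any(abs_before <= 0)) stop("abs_before must be positive")
  if (any(abs_after < 0)) stop("abs_after must be non-negative")
  100 * abs_after / abs_before
}

#' Construct a decoloration time series
#'
#' Residual pigment (percent of initial absorbance at 530 nm) against
#' incubation time.  When the series starts at t = 0 the first value is the
#' normalization point and must be 100.
#'
#' @param times incubation times in minutes, non-negative and increasing.
#' @param pigment residual pigment in percent, >= 0.
#' @param construct_label character label.
#' @return An object of class `decoloration_series` (also a data frame with
#'   columns `time_min`, `pigment_pct`).
#' @export
decoloration_series <- function(times, pigment, construct_label = "") {
  if (length(times) != length(pigment)) stop("times and pigment lengths differ")
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be non-negative and increasing")
  }
  if (any(pigment < 0)) stop("pigment values must be non-negative")
  if (times[1] == 0 && abs(pigment[1] - 100) > 1e-9) {
    stop("pigment at t = 0 must be 100 (it is the normalization point)")
  }
  out <- data.frame(time_min = as.numeric(times), pigment_pct = as.numeric(pigment))
  attr(out, "construct_label") <- construct_label
  class(out) <- c("decoloration_series", "data.frame")
  out
}

#' Fit a single-exponential decoloration decay
#'
#' Nonlinear least-squares fit of `P(t) = P0 * exp(-k * t)` (no offset or
#' plateau term) to a decoloration series, initialised from a log-linear
#' regression.  Returns the rate constant k (min^-1) and the half-life
#' `tau_half = ln(2) / k`.
#'
#' @param series a [decoloration_series], or a data frame with columns
#'   `time_min` and `pigment_pct`.
#' @return An object of class `decay_fit`: `k`, `k_se`, `p0`, `tau_half`
#'   (minutes; `Inf` when k = 0), `fit_sse`, `n_points`.
#' @export
fit_decoloration <- function(series) {
  t <- series$time_min; p <- series$pigment_pct
  if (is.null(t) || is.null(p)) stop("series needs columns time_min and pigment_pct")
  if (length(t) < 3L) stop("need at least 3 time points")
  if (p[1] <= 0) stop("initial pigment must be positive")
  if (all(p == 0)) stop("all-zero pigment series")
  if (stats::sd(p) == 0) {
    # constant series: no decay
    return(structure(list(k = 0, k_se = 0, p0 = p[1], tau_half = Inf,
                          fit_sse = 0, n_points = length(t)),
                     class = "decay_fit"))
  }
  pos <- p > 0
  init <- stats::lm(log(p[pos]) ~ t[pos])
  k0 <- max(-unname(stats::coef(init)[2]), 1e-6)
  p00 <- exp(unname(stats::coef(init)[1]))
  fit <- minpack.lm::nlsLM(p ~ p0 * exp(-k * t),
                           start = list(p0 = p00, k = k0),
                           lower = c(p0 = 0, k = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  k <- unname(est["k"])
  structure(list(k = k, k_se = unname(se["k"]), p0 = unname(est["p0"]),
                 tau_half = if (k > 0) log(2) / k else Inf,
                 fit_sse = sum(stats::resid(fit)^2), n_points = length(t),
                 model = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: k = %.4g min^-1 (se %.2g), tau_1/2 = %.3g min, n = %d, sse = %.3g\n",
    x$k, x$k_se, x$tau_half, x$n_points, x$fit_sse))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(p0 = object$p0, k = object$k)

#' @export
predict.decay_fit <- function(object, times, ...) {
  object$p0 * exp(-object$k * times)
}

#' Construct a DSC thermogram
#'
#' @param temperatures scan temperatures in degrees C, strictly increasing.
#' @param signal heat signal (raw instrument units, or molar heat capacity
#'   after normalization).
#' @param stage processing stage: `"raw"`, `"buffer_subtracted"`,
#'   `"normalized"` or `"baseline_subtracted"`.
#' @return An object of class `dsc_thermogram`.
#' @export
dsc_thermogram <- function(temperatures, signal, stage = "raw") {
  if (length(temperatures) != length(signal)) stop("length mismatch")
  if (any(diff(temperatures) <= 0)) stop("temperatures must be strictly increasing")
  stage <- match.arg(stage, c("raw", "buffer_subtracted", "normalized",
                              "baseline_subtracted"))
  structure(list(temperatures = as.numeric(temperatures),
                 signal = as.numeric(signal), stage = stage),
            class = "dsc_thermogram")
}

#' @export
print.dsc_thermogram <- function(x, ...) {
  cat(sprintf("dsc_thermogram (%s): %.1f-%.1f degC, %d points\n",
              x$stage, min(x$temperatures), max(x$temperatures),
              length(x$temperatures)))
  invisible(x)
}

#' Process a raw DSC thermogram
#'
#' Standard processing chain: the buffer reference (interpolated onto the
#' sample grid) is subtracted, the signal is divided by the molar protein
#' concentration, and a baseline interpolated between the pre- and
#' post-transition windows is subtracted.  The baseline is a least-squares
#' straight line through the data inside the two windows by default; a
#' cubic polynomial is available.
#'
#' @param sample,buffer raw [dsc_thermogram] objects on overlapping
#'   temperature grids.
#' @param molar_conc molar protein concentration (mol/L, > 0).
#' @param baseline_windows list with elements `pre` and `post`, each a
#'   temperature pair in degrees C.  Default: first and last 10 degrees of
#'   the scan.
#' @param baseline `"linear"` (default) or `"cubic"`.
#' @return A `baseline_subtracted` [dsc_thermogram].
#' @export
process_dsc <- function(sample, buffer, molar_conc,
                        baseline_windows = NULL,
                        baseline = c("linear", "cubic")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(sample, "dsc_thermogram"), inherits(buffer, "dsc_thermogram"))
  if (molar_conc <= 0) stop("molar_conc must be positive")
  lo <- max(min(sample$temperatures), min(buffer$temperatures))
  hi <- min(max(sample$temperatures), max(buffer$temperatures))
  if (lo >= hi) stop("sample and buffer temperature grids do not overlap")
  keep <- sample$temperatures >= lo & sample$temperatures <= hi
  temp <- sample$temperatures[keep]
  buf <- stats::approx(buffer$temperatures, buffer$signal, xout = temp)$y
  sig <- (sample$signal[keep] - buf) / molar_conc
  if (is.null(baseline_windows)) {
    baseline_windows <- list(pre = c(temp[1], temp[1] + 10),
                             post = c(temp[length(temp)] - 10, temp[length(temp)]))
  }
  in_win <- (temp >= baseline_windows$pre[1] & temp <= baseline_windows$pre[2]) |
    (temp >= baseline_windows$post[1] & temp <= baseline_windows$post[2])
  if (sum(in_win) < 4L) stop("baseline windows contain too few points")
  peak_t <- temp[which.max(sig)]
  if ((peak_t >= baseline_windows$pre[1] && peak_t <= baseline_windows$pre[2]) ||
      (peak_t >= baseline_windows$post[1] && peak_t <= baseline_windows$post[2])) {
    warning("signal maximum lies inside a baseline window; ",
            "check the window placement")
  }
  fit <- if (baseline == "linear") {
    stats::lm(sig[in_win] ~ temp[in_win])
  } else {
    stats::lm(sig[in_win] ~ poly(temp[in_win], 3, raw = TRUE))
  }
  base <- if (baseline == "linear") {
    cbind(1, temp) %*% stats::coef(fit)
  } else {
    cbind(1, temp, temp^2, temp^3) %*% stats::coef(fit)
  }
  dsc_thermogram(temp, sig - as.numeric(base), stage = "baseline_subtracted")
}

#' Melting temperature at the peak top
#'
#' Temperature of the global maximum of a processed heat-capacity curve, on
#' the sampled grid (no sub-grid interpolation: the peak top is taken
#' literally, so the grid spacing limits the reported precision).
#'
#' @param thermogram a `baseline_subtracted` [dsc_thermogram].
#' @return Tm in degrees C.
#' @export
extract_tm <- function(thermogram) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  if (thermogram$stage != "baseline_subtracted") {
    stop("extract_tm expects a baseline_subtracted thermogram; run process_dsc")
  }
  s <- thermogram$signal
  if (stats::sd(s) == 0) stop("flat curve: no peak")
  i <- which.max(s)
  if (i == 1L || i == length(s)) {
    stop("signal maximum at the scan boundary: no interior peak")
  }
  thermogram$temperatures[i]
}

#' Classify constructs as thermo-stabilized
#'
#' A mutant is stabilized when its Tm exceeds the wild-type Tm by not less
#' than `delta_threshold` (boundary inclusive); constructs without a Tm are
#' `"unmeasured"`.
#'
#' @param records data frame with columns `construct` and `tm_mean`
#'   (degrees C; `NA` when not measured).
#' @param wild_type_label construct label of the wild type.
#' @param delta_threshold minimum Tm increase in degrees C (default 1).
#' @return Named character vector over the non-wild-type constructs with
#'   values `"stabilized"`, `"not_stabilized"` or `"unmeasured"`.
#' @export
classify_stabilized <- function(records, wild_type_label = "WT",
                                delta_threshold = 1.0) {
  if (!all(c("construct", "tm_mean") %in% names(records))) {
    stop("records needs columns construct and tm_mean")
  }
  wt <- records$tm_mean[records$construct == wild_type_label]
  if (!length(wt) || is.na(wt[1])) stop("wild-type record with a Tm is required")
  mut <- records[records$construct != wild_type_label, , drop = FALSE]
  out <- ifelse(is.na(mut$tm_mean), "unmeasured",
                ifelse(mut$tm_mean - wt[1] >= delta_threshold,
                       "stabilized", "not_stabilized"))
  stats::setNames(out, mut$construct)
}
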