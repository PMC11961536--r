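#' Construct a spread series
#'
#' Internal container for the overtone-spread statistic and series derived
#' from it (normalized spread, second-derivative curves).
#'
#' @param time Time grid, minutes.
#' @param value Series values: deltaD in 1e-6 units, dimensionless once
#'   normalized, 1/min^2 for derivative curves.
#' @param normalized Logical flag.
#' @param t_ref Normalization reference time (start of the second injection),
#'   minutes; NA when not normalized.
#' @return An object of class `"spread_series"`.
#' @keywords internal
spread_series <- function(time, value, normalized = FALSE, t_ref = NA_real_) {
  stopifnot(length(time) == length(value), !is.unsorted(time, strictly = TRUE))
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 normalized = isTRUE(normalized), t_ref = t_ref),
            class = "spread_series")
}

#' @export
print.spread_series <- function(x, ...) {
  cat("spread series: ", length(x$time), " samples, t = ",
      format(x$time[1L]), " .. ", format(x$time[length(x$time)]), " min",
      if (x$normalized) sprintf(", normalized (t_ref = %g min)", x$t_ref),
      "\n", sep = "")
  invisible(x)
}

#' Overtone-spread statistic deltaD = DeltaD3 - DeltaD11
#'
#' The single-parameter lysis indicator: the pointwise difference between
#' the third- and eleventh-overtone dissipation traces. Because the shear
#' wave of the 3rd overtone penetrates about twice as deep (~140 nm vs
#' ~70 nm in water) as that of the 11th, the spread grows with the effective
#' thickness of the soft bacterial film and collapses when the film is lysed
#' to thin rigid debris.
#'
#' @param exp A [qcmd_experiment()] containing overtones 3 and 11.
#' @return An unnormalized `"spread_series"` in 1e-6 units.
#' @export
delta_d_spread <- function(exp) {
  stopifnot(inherits(exp, "qcmd_experiment"))
  d3 <- get_overtone_series(exp, 3, "dissipation")
  d11 <- get_overtone_series(exp, 11, "dissipation")
  spread_series(experiment_time(exp), d3 - d11)
}

#' Normalize a spread series to its pre-injection maximum
#'
#' Divides by the maximum of the series over `t < t_ref` (the growth phase
#' before the second injection). This removes the strong sensor-to-sensor
#' scale differences: every normalized trace reaches 1 during initial growth
#' regardless of sensor sensitivity. Normalizing an already-normalized
#' series with the same reference is the identity.
#'
#' @param series A `"spread_series"`.
#' @param t_ref Reference time (start of the second injection), min.
#' @return A normalized `"spread_series"`.
#' @export
normalize_spread <- function(series, t_ref) {
  stopifnot(inherits(series, "spread_series"))
  pre <- series$value[series$time < t_ref]
  if (length(pre) == 0L) {
    stop("no samples before t_ref = ", t_ref, call. = FALSE)
  }
  mx <- max(pre)
  if (!is.finite(mx) || mx <= 0) {
    stop("degenerate baseline: pre-injection maximum of deltaD is not ",
         "positive; no bacterial film formed", call. = FALSE)
  }
  spread_series(series$time, series$value / mx, normalized = TRUE,
                t_ref = t_ref)
}

#' Smoothed second derivative of a spread series
#'
#' Moving-average smoothing (symmetric window of `2 * halfwidth + 1`
#' samples; only positions where the full window fits are kept, so the
#' series loses `halfwidth` samples at each end) followed by central second
#' differences on the uniform grid; the two endpoints of the smoothed
#' series use one-sided second differences. Exact for quadratics.
#'
#' @param series A `"spread_series"` on a uniform grid.
#' @param window Length-2 numeric `c(start, end)` in minutes; the derivative
#'   is computed over samples with `start <= t <= end`. Default: the whole
#'   series.
#' @param halfwidth Smoothing halfwidth in samples (default 5, i.e. 2.5 min
#'   at the default 0.5 min grid step). 0 disables smoothing.
#' @return A `"spread_series"` holding the derivative curve, units 1/min^2
#'   (times the input units).
#' @export
second_derivative <- function(series, window = NULL, halfwidth = 5) {
  stopifnot(inherits(series, "spread_series"), halfwidth >= 0)
  t <- series$time; y <- series$value
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  n <- length(t)
  if (n - 2L * halfwidth < 5L) {
    stop("too few samples in window for a second derivative ",
         "(need >= 5 after smoothing)", call. = FALSE)
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-8 * dt[1L]) {
    stop("second_derivative requires a uniform time grid", call. = FALSE)
  }
  dt <- dt[1L]
  # symmetric moving average, full windows only
  if (halfwidth > 0) {
    k <- as.integer(halfwidth)
    idx <- (k + 1L):(n - k)
    sm <- vapply(idx, function(i) mean(y[(i - k):(i + k)]), numeric(1))
    t <- t[idx]
    n <- length(t)
  } else {
    sm <- y
  }
  d2 <- numeric(n)
  i <- 2:(n - 1L)
  d2[i] <- (sm[i - 1L] - 2 * sm[i] + sm[i + 1L]) / dt^2
  d2[1L] <- (sm[1L] - 2 * sm[2L] + sm[3L]) / dt^2
  d2[n] <- (sm[n] - 2 * sm[n - 1L] + sm[n - 2L]) / dt^2
  spread_series(t, d2, normalized = FALSE)
}

#' Drop fraction of the normalized spread across phage injection
#'
#' 1 minus the ratio of the minimum normalized deltaD over the injection-
#' through-flush window (plus a settling buffer) to its value at the start
#' of the second injection. Lysis of a T7-like film gives about 0.8,
#' independently of titer; a negative value signals continued growth during
#' the injection.
#'
#' @param norm_series A normalized `"spread_series"` spanning the second
#'   injection through the final flush.
#' @param schedule The experiment's [phase_schedule()].
#' @param settling_buffer Minutes past the end of the final flush over which
#'   the minimum is still searched (default 10), capturing the post-flush
#'   settling before the plateau is read.
#' @return The drop fraction (dimensionless, unclamped).
#' @export
drop_fraction <- function(norm_series, schedule, settling_buffer = 10) {
  stopifnot(inherits(norm_series, "spread_series"),
            inherits(schedule, "phase_schedule"))
  inj <- phase_window(schedule, "second_injection")
  fl2 <- phase_window(schedule, "flush_2")
  ref <- readout_at(norm_series, unname(inj["start"]))
  if (!is.finite(ref) || ref <= 0) {
    stop("degenerate baseline: deltaD at the second injection start is not ",
         "positive", call. = FALSE)
  }
  hi <- min(unname(fl2["end"]) + settling_buffer,
            norm_series$time[length(norm_series$time)])
  # strictly after the reference point, so a rising trace yields a negative
  # drop rather than being clamped at zero by its own reference sample
  keep <- norm_series$time > unname(inj["start"]) & norm_series$time <= hi
  if (!any(keep)) stop("series does not cover the injection window", call. = FALSE)
  1 - min(norm_series$value[keep]) / ref
}

#' Read the spread at a fixed timepoint
#'
#' Linear interpolation between the bracketing samples; a grid point is
#' returned exactly.
#'
#' @param series A `"spread_series"`.
#' @param t Timepoint in minutes, within the series span.
#' @return Interpolated value (scalar).
#' @export
readout_at <- function(series, t) {
  stopifnot(inherits(series, "spread_series"), length(t) == 1L)
  tt <- series$time
  if (t < tt[1L] || t > tt[length(tt)]) {
    stop("readout time ", t, " min is outside the series span [",
         tt[1L], ", ", tt[length(tt)], "]", call. = FALSE)
  }
  stats::approx(tt, series$value, xout = t)$y
}

#' Classify a normalized spread trace as lytic or non-lytic
#'
#' The detection procedure: compute the smoothed second derivative of the
#' normalized deltaD curve over the period after the final flush with
#' phage-free medium, then call the trace lytic if the chosen statistic
#' (mean or sum of the derivative curve) is positive. Lysed films produce
#' convex post-flush curves (decay tail and early survivor regrowth), hence
#' mostly positive second derivatives; undisturbed films saturate
#' concavely, hence mostly negative ones. An exactly zero statistic is
#' called non-lytic.
#'
#' @param norm_series A normalized `"spread_series"` covering the post-flush
#'   window.
#' @param schedule The experiment's [phase_schedule()].
#' @param rule Decision statistic: `"mean_sign"` (default) or `"sum_sign"`.
#' @param halfwidth Smoothing halfwidth in samples for
#'   [second_derivative()].
#' @param readout_time Fixed-timepoint readout, min (default 240, after the
#'   injection-induced drop has saturated).
#' @param settling_buffer Passed to [drop_fraction()].
#' @return An object of class `"lysis_call"`: label (`"lytic"`/
#'   `"non_lytic"`), `derivative_sum`, `derivative_mean`, `drop_fraction`,
#'   `readout_240`, and a `diagnostics` list (decision window, rule,
#'   derivative curve).
#' @export
classify_lysis <- function(norm_series, schedule,
                           rule = c("mean_sign", "sum_sign"),
                           halfwidth = 5, readout_time = 240,
                           settling_buffer = 10) {
  stopifnot(inherits(norm_series, "spread_series"),
            inherits(schedule, "phase_schedule"))
  rule <- match.arg(rule)
  if (!norm_series$normalized) {
    stop("classify_lysis expects a normalized spread series; see ",
         "normalize_spread()", call. = FALSE)
  }
  fl2 <- phase_window(schedule, "flush_2")
  t_end <- norm_series$time[length(norm_series$time)]
  if (unname(fl2["end"]) >= t_end) {
    stop("series does not extend past the final flush", call. = FALSE)
  }
  deriv <- second_derivative(norm_series,
                             window = c(unname(fl2["end"]), t_end),
                             halfwidth = halfwidth)
  dsum <- sum(deriv$value)
  dmean <- mean(deriv$value)
  stat <- if (rule == "mean_sign") dmean else dsum
  label <- if (stat > 0) "lytic" else "non_lytic"
  structure(list(
    label = label,
    derivative_sum = dsum,
    derivative_mean = dmean,
    drop_fraction = drop_fraction(norm_series, schedule, settling_buffer),
    readout_240 = readout_at(norm_series, min(readout_time, t_end)),
    diagnostics = list(rule = rule, statistic = stat,
                       window = c(unname(fl2["end"]), t_end),
                       halfwidth = halfwidth, readout_time = readout_time,
                       derivative = deriv)
  ), class = "lysis_call")
}

#' @export
print.lysis_call <- function(x, ...) {
  cat("lysis call: ", toupper(x$label), "\n", sep = "")
  cat(sprintf("  decision: %s of d2(deltaD)/dt2 over [%g, %g] min = %.3g\n",
              sub("_sign$", "", x$diagnostics$rule), x$diagnostics$window[1],
              x$diagnostics$window[2], x$diagnostics$statistic))
  cat(sprintf("  drop fraction across injection: %.3f\n", x$drop_fraction))
  cat(sprintf("  normalized deltaD at %g min: %.3f\n",
              x$diagnostics$readout_time, x$readout_240))
  invisible(x)
}

#' End-to-end lysis call for one experiment
#'
#' Convenience wrapper: spread, normalization at the second-injection start,
#' classification.
#'
#' @param exp A [qcmd_experiment()] with overtones 3 and 11.
#' @param ... Passed to [classify_lysis()].
#' @return A `"lysis_call"`.
#' @export
detect_lysis <- function(exp, ...) {
  stopifnot(inherits(exp, "qcmd_experiment"))
  inj <- phase_window(exp$schedule, "second_injection")
  ns <- normalize_spread(delta_d_spread(exp), t_ref = unname(inj["start"]))
  classify_lysis(ns, exp$schedule, ...)
}

#' Welch comparison of two readout groups
#'
#' Two-sample, two-tailed Welch t-test (unequal variances) between scalar
#' readouts of two experimental arms, with the conventional significance
#' stars.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return An object of class `"group_comparison"`: group means and SDs,
#'   `t_statistic`, `degrees_of_freedom`, `p_value` and `stars`
#'   (`"ns"`, `"*"` p<0.05, `"**"` p<0.01, `"***"` p<0.001).
#' @export
group_compare <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    # t.test errors on two constant equal groups; this is the t = 0 limit
    ht <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = 1)
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                        alternative = "two.sided")
  }
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  structure(list(mean_a = mean(group_a), sd_a = stats::sd(group_a),
                 n_a = length(group_a),
                 mean_b = mean(group_b), sd_b = stats::sd(group_b),
                 n_b = length(group_b),
                 t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = p, stars = stars),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group A: %.3f +/- %.3f (n=%d)   group B: %.3f +/- %.3f (n=%d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("Welch two-tailed t-test: t = %.3f, df = %.2f, p = %.3g [%s]\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$stars))
  invisible(x)
}
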