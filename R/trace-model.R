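#' A single overtone's paired frequency/dissipation time series
#'
#' @param overtone Odd integer overtone number (>= 3 for analysis use; the
#'   fundamental n = 1 is accepted for completeness).
#' @param time Strictly increasing time grid in minutes from experiment start.
#' @param delta_f Frequency shift per time point, Hz (raw per-overtone shift,
#'   not divided by the overtone number).
#' @param delta_D Dissipation shift per time point, in the conventional
#'   1e-6 units.
#' @return An object of class `"overtone_trace"`.
#' @export
overtone_trace <- function(overtone, time, delta_f, delta_D) {
  overtone <- as.integer(overtone)
  if (length(overtone) != 1L || overtone < 1L || overtone %% 2L == 0L) {
    stop("overtone number must be a single odd integer >= 1", call. = FALSE)
  }
  if (length(time) < 2L || any(diff(time) <= 0)) {
    stop("time grid must be strictly increasing with at least 2 samples",
         call. = FALSE)
  }
  if (length(delta_f) != length(time) || length(delta_D) != length(time)) {
    stop("delta_f and delta_D must have the same length as time", call. = FALSE)
  }
  structure(list(overtone = overtone, time = as.numeric(time),
                 delta_f = as.numeric(delta_f), delta_D = as.numeric(delta_D)),
            class = "overtone_trace")
}

# Canonical phase names in protocol order.
PHASE_NAMES <- c("baseline_pbs", "bacteria_injection", "flush_1",
                 "growth_static", "second_injection", "flush_2", "post_static")

#' Phase schedule of a QCM-D assay
#'
#' Ordered, labelled time windows describing what was in the flow cell and
#' whether the pump was running. Windows are half-open `[start, end)` in
#' minutes from experiment start, contiguous and non-overlapping, and must
#' appear in protocol order: baseline_pbs, bacteria_injection, flush_1,
#' growth_static, second_injection, flush_2, post_static (a clipped schedule
#' may contain a contiguous subset).
#'
#' @param phases A data.frame with columns `name`, `start`, `end`, `medium`
#'   (one of PBS, medium, bacteria_in_medium, phage_in_medium) and
#'   `flow_rate` (uL/min, 0 for static).
#' @return An object of class `"phase_schedule"` (a validated data.frame).
#' @seealso [default_schedule()]
#' @export
phase_schedule <- function(phases) {
  need <- c("name", "start", "end", "medium", "flow_rate")
  if (!is.data.frame(phases) || !all(need %in% names(phases))) {
    stop("phases must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  phases <- as.data.frame(phases)[need]
  if (nrow(phases) < 1L) stop("schedule needs at least one phase", call. = FALSE)
  idx <- match(phases$name, PHASE_NAMES)
  if (anyNA(idx)) {
    stop("unknown phase name(s): ",
         paste(setdiff(phases$name, PHASE_NAMES), collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(idx) <= 0)) {
    stop("phases must appear in protocol order without repeats", call. = FALSE)
  }
  if (any(phases$end <= phases$start)) {
    stop("each phase must have end > start", call. = FALSE)
  }
  if (nrow(phases) > 1L &&
      any(abs(phases$start[-1L] - phases$end[-nrow(phases)]) > 1e-9)) {
    stop("phases must be contiguous and non-overlapping", call. = FALSE)
  }
  media <- c("PBS", "medium", "bacteria_in_medium", "phage_in_medium")
  if (!all(phases$medium %in% media)) {
    stop("medium must be one of ", paste(media, collapse = ", "), call. = FALSE)
  }
  if (any(phases$flow_rate < 0)) stop("flow_rate must be >= 0", call. = FALSE)
  if (all(c("growth_static", "second_injection") %in% phases$name)) {
    gs <- phases[phases$name == "growth_static", ]
    si <- phases[phases$name == "second_injection", ]
    if (si$start < gs$end) {
      stop("second_injection must start after growth_static", call. = FALSE)
    }
  }
  rownames(phases) <- NULL
  structure(phases, class = c("phase_schedule", "data.frame"))
}

#' The standard assay schedule
#'
#' The protocol the pipeline is designed around: 20 min PBS baseline, 30 min
#' bacterial adsorption under flow, 15 min medium flush, 2 h static growth,
#' 20 min second injection (phage suspension, or plain medium for controls),
#' 15 min flush, then 3 h static incubation; pump at 30 uL/min during flow
#' phases. All durations are parameters.
#'
#' @param pbs,bacteria,flush1,growth,injection,flush2,post Phase durations in
#'   minutes.
#' @param flow_rate Pump rate during flow phases, uL/min.
#' @param second_medium Medium of the second injection, default
#'   `"phage_in_medium"` (use `"medium"` for a bacteria-only control).
#' @return A [phase_schedule()].
#' @export
default_schedule <- function(pbs = 20, bacteria = 30, flush1 = 15,
                             growth = 120, injection = 20, flush2 = 15,
                             post = 180, flow_rate = 30,
                             second_medium = "phage_in_medium") {
  d <- c(pbs, bacteria, flush1, growth, injection, flush2, post)
  ends <- cumsum(d)
  starts <- c(0, ends[-length(ends)])
  phase_schedule(data.frame(
    name = PHASE_NAMES,
    start = starts,
    end = ends,
    medium = c("PBS", "bacteria_in_medium", "medium", "medium",
               second_medium, "medium", "medium"),
    flow_rate = c(flow_rate, flow_rate, flow_rate, 0, flow_rate, flow_rate, 0),
    stringsAsFactors = FALSE
  ))
}

#' Look up one phase's window
#'
#' @param schedule A [phase_schedule()].
#' @param name A canonical phase name.
#' @return Named numeric `c(start, end)` in minutes.
#' @export
phase_window <- function(schedule, name) {
  stopifnot(inherits(schedule, "phase_schedule"))
  row <- schedule[schedule$name == name, ]
  if (nrow(row) != 1L) {
    stop("phase '", name, "' not present in schedule", call. = FALSE)
  }
  c(start = row$start, end = row$end)
}

#' A complete multi-overtone QCM-D experiment
#'
#' The unit the pipeline consumes: one trace per overtone on a shared time
#' grid, plus the phase schedule and metadata. Full analysis needs overtones
#' 3, 5, 7, 9 and 11; the lysis statistic itself needs 3 and 11.
#'
#' @param traces A list of [overtone_trace()] objects, all on an identical
#'   time grid.
#' @param schedule A [phase_schedule()] whose windows lie within the grid
#'   span.
#' @param sensor_id Free-text sensor identifier.
#' @param fundamental_frequency Fundamental resonance, Hz (default 5 MHz).
#' @param label Optional ground-truth tag for simulated data: `"control"`,
#'   `"non_infectious"` or `"infectious"`.
#' @return An object of class `"qcmd_experiment"`.
#' @export
qcmd_experiment <- function(traces, schedule, sensor_id = "sensor",
                            fundamental_frequency = 5e6, label = NULL) {
  if (!is.list(traces) || length(traces) == 0L ||
      !all(vapply(traces, inherits, logical(1), "overtone_trace"))) {
    stop("traces must be a non-empty list of overtone_trace objects",
         call. = FALSE)
  }
  stopifnot(inherits(schedule, "phase_schedule"))
  if (!is.null(label) &&
      !label %in% c("control", "non_infectious", "infectious")) {
    stop("label must be control, non_infectious or infectious", call. = FALSE)
  }
  grid <- traces[[1L]]$time
  same <- vapply(traces, function(tr) {
    length(tr$time) == length(grid) && all(tr$time == grid)
  }, logical(1))
  if (!all(same)) {
    stop("all traces must share an identical time grid", call. = FALSE)
  }
  ns <- vapply(traces, `[[`, integer(1), "overtone")
  if (anyDuplicated(ns)) stop("duplicate overtone numbers", call. = FALSE)
  names(traces) <- as.character(ns)
  tol <- 1e-9
  if (min(schedule$start) < grid[1L] - tol ||
      max(schedule$end) > grid[length(grid)] + diff(grid)[1L] + tol) {
    stop("schedule windows must lie within the time grid span", call. = FALSE)
  }
  structure(list(sensor_id = sensor_id,
                 fundamental_frequency = fundamental_frequency,
                 traces = traces[order(ns)], schedule = schedule,
                 label = label),
            class = "qcmd_experiment")
}

#' Shared time grid of an experiment
#' @param exp A [qcmd_experiment()].
#' @return Numeric vector of times in minutes.
#' @export
experiment_time <- function(exp) {
  stopifnot(inherits(exp, "qcmd_experiment"))
  exp$traces[[1L]]$time
}

#' Overtone numbers present in an experiment
#' @param exp A [qcmd_experiment()].
#' @return Sorted integer vector.
#' @export
overtones <- function(exp) {
  stopifnot(inherits(exp, "qcmd_experiment"))
  as.integer(names(exp$traces))
}

#' Extract one overtone's channel series
#'
#' @param exp A [qcmd_experiment()].
#' @param n Overtone number; must be present in `exp`.
#' @param channel `"frequency"` (Deltaf, Hz) or `"dissipation"` (DeltaD,
#'   1e-6 units).
#' @return Numeric vector aligned to the shared time grid.
#' @export
get_overtone_series <- function(exp, n,
                                channel = c("frequency", "dissipation")) {
  stopifnot(inherits(exp, "qcmd_experiment"))
  channel <- match.arg(channel)
  key <- as.character(as.integer(n))
  if (!key %in% names(exp$traces)) {
    stop("overtone absent: n = ", n, " not in experiment (have ",
         paste(names(exp$traces), collapse = ", "), ")", call. = FALSE)
  }
  tr <- exp$traces[[key]]
  if (channel == "frequency") tr$delta_f else tr$delta_D
}

#' Restrict an experiment to a time window
#'
#' Cuts every trace to the half-open window `[t_start, t_end)` and clips the
#' schedule to it (phases falling entirely outside are dropped). Times are
#' kept absolute, not re-zeroed.
#'
#' @param exp A [qcmd_experiment()].
#' @param t_start,t_end Window bounds in minutes, `t_start < t_end`.
#' @return A [qcmd_experiment()] restricted to the window.
#' @export
slice_window <- function(exp, t_start, t_end) {
  stopifnot(inherits(exp, "qcmd_experiment"))
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  grid <- experiment_time(exp)
  keep <- grid >= t_start & grid < t_end
  if (sum(keep) < 2L) {
    stop("empty window: [", t_start, ", ", t_end,
         ") contains fewer than 2 samples", call. = FALSE)
  }
  traces <- lapply(exp$traces, function(tr) {
    overtone_trace(tr$overtone, tr$time[keep], tr$delta_f[keep],
                   tr$delta_D[keep])
  })
  sch <- as.data.frame(exp$schedule)
  sch$start <- pmax(sch$start, min(grid[keep]))
  sch$end <- pmin(sch$end, t_end)
  sch <- sch[sch$end > sch$start, , drop = FALSE]
  if (nrow(sch) == 0L) {
    stop("empty window: no schedule phase overlaps [", t_start, ", ", t_end,
         ")", call. = FALSE)
  }
  qcmd_experiment(traces, phase_schedule(sch), sensor_id = exp$sensor_id,
                  fundamental_frequency = exp$fundamental_frequency,
                  label = exp$label)
}

#' @export
print.qcmd_experiment <- function(x, ...) {
  grid <- experiment_time(x)
  cat("QCM-D experiment '", x$sensor_id, "'\n", sep = "")
  cat("  overtones: ", paste(names(x$traces), collapse = ", "),
      " | f0 = ", x$fundamental_frequency / 1e6, " MHz\n", sep = "")
  cat("  time: ", format(grid[1L]), " .. ", format(grid[length(grid)]),
      " min (", length(grid), " samples)\n", sep = "")
  cat("  phases: ", paste(x$schedule$name, collapse = " > "), "\n", sep = "")
  if (!is.null(x$label)) cat("  ground truth: ", x$label, "\n", sep = "")
  invisible(x)
}

#' Plot the raw overtone traces of an experiment
#'
#' Two stacked panels (Deltaf, DeltaD) with one line per overtone and the
#' phase boundaries marked.
#'
#' @param x A [qcmd_experiment()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.qcmd_experiment <- function(x, ...) {
  grid <- experiment_time(x)
  ns <- overtones(x)
  fmat <- vapply(ns, function(n) get_overtone_series(x, n, "frequency"),
                 numeric(length(grid)))
  dmat <- vapply(ns, function(n) get_overtone_series(x, n, "dissipation"),
                 numeric(length(grid)))
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(length(ns), "Dark 3")
  graphics::matplot(grid, fmat, type = "l", lty = 1, col = cols,
                    xlab = "time (min)", ylab = expression(Delta * f ~ "(Hz)"),
                    main = x$sensor_id, ...)
  graphics::abline(v = x$schedule$start[-1L], col = "grey80", lty = 3)
  graphics::legend("bottomleft", legend = paste0("n=", ns), col = cols,
                   lty = 1, cex = 0.7, bty = "n")
  graphics::matplot(grid, dmat, type = "l", lty = 1, col = cols,
                    xlab = "time (min)",
                    ylab = expression(Delta * D ~ "(1e-6)"), ...)
  graphics::abline(v = x$schedule$start[-1L], col = "grey80", lty = 3)
  invisible(x)
}
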