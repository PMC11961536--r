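#' Configuration of a screening run
#'
#' Declarative description of a simulated (or re-analyzed) screen: the assay
#' schedule, the replicate panel, simulator overrides, analysis parameters
#' and the master seed.
#'
#' @param panel A data.frame with columns `scenario`, `titer` (NA for the
#'   scenario default) and `n` (replicates, >= 1).
#' @param schedule A [phase_schedule()] used for every replicate (controls
#'   get plain medium at the second injection automatically).
#' @param sim Named list of [sim_params()] overrides applied to every
#'   replicate.
#' @param analysis Named list of analysis parameters: `rule`, `halfwidth`,
#'   `readout_time`, `settling_buffer` (missing entries take the
#'   [classify_lysis()] defaults).
#' @param master_seed Integer master seed for the panel.
#' @param output_dir Optional directory; when set, [run_screen()] writes
#'   `report.csv` plus overlay and readout plots there.
#' @return An object of class `"screen_config"`.
#' @export
screen_config <- function(panel = data.frame(
                            scenario = c("control", "infectious",
                                         "infectious", "infectious",
                                         "non_infectious"),
                            titer = c(NA, 8e7, 2e6, 4e5, NA),
                            n = c(2L, 1L, 1L, 1L, 1L)),
                          schedule = NULL,
                          sim = list(),
                          analysis = list(),
                          master_seed = 1L,
                          output_dir = NULL) {
  stopifnot(is.data.frame(panel),
            all(c("scenario", "n") %in% names(panel)))
  if (!"titer" %in% names(panel)) panel$titer <- NA_real_
  if (any(panel$n < 1)) stop("replicate counts must be >= 1", call. = FALSE)
  if (!all(panel$scenario %in% c("control", "infectious", "non_infectious"))) {
    stop("unknown scenario in panel", call. = FALSE)
  }
  known <- c("rule", "halfwidth", "readout_time", "settling_buffer")
  if (length(analysis) > 0L && !all(names(analysis) %in% known)) {
    stop("unknown analysis parameter(s): ",
         paste(setdiff(names(analysis), known), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "phase_schedule"))
    rt <- analysis$readout_time %||% 240
    if (rt < min(schedule$start) || rt > max(schedule$end)) {
      stop("readout time must lie within the schedule span", call. = FALSE)
    }
  }
  structure(list(panel = panel, schedule = schedule, sim = sim,
                 analysis = analysis, master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "screen_config")
}

#' Read a screening configuration from a YAML document
#'
#' Keys: `master_seed`; `panel` (list of `{scenario, titer, n}` entries);
#' `schedule` (phase durations for [default_schedule()]: pbs, bacteria,
#' flush1, growth, injection, flush2, post, flow_rate); `sim` (parameter
#' overrides); `analysis`; `output_dir`.
#'
#' @param path Path to the YAML file.
#' @return A [screen_config()].
#' @export
read_screen_config <- function(path) {
  doc <- yaml::read_yaml(path)
  panel <- if (is.null(doc$panel)) NULL else {
    do.call(rbind, lapply(doc$panel, function(e) {
      data.frame(scenario = e$scenario,
                 titer = if (is.null(e$titer)) NA_real_ else as.numeric(e$titer),
                 n = as.integer(e$n %||% 1L), stringsAsFactors = FALSE)
    }))
  }
  schedule <- if (is.null(doc$schedule)) NULL else {
    do.call(default_schedule, doc$schedule)
  }
  args <- list(schedule = schedule,
               sim = doc$sim %||% list(),
               analysis = doc$analysis %||% list(),
               master_seed = doc$master_seed %||% 1L,
               output_dir = doc$output_dir)
  if (!is.null(panel)) args$panel <- panel
  do.call(screen_config, args)
}

# 32-bit FNV-1a over the serialized config; stable within an R version,
# used only to assert that two reports came from the same configuration.
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- ((16777619 * h1) %% 65536) * 65536 + 16777619 * h0
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

build_design <- function(config) {
  rows <- config$panel
  design <- list()
  for (i in seq_len(nrow(rows))) {
    for (j in seq_len(rows$n[i])) {
      args <- config$sim
      args$scenario <- rows$scenario[i]
      if (!is.na(rows$titer[i])) args$titer <- rows$titer[i]
      if (!is.null(config$schedule)) {
        sch <- as.data.frame(config$schedule)
        if (rows$scenario[i] == "control") {
          sch$medium[sch$name == "second_injection"] <- "medium"
        }
        args$schedule <- phase_schedule(sch)
      }
      design[[length(design) + 1L]] <- do.call(sim_params, args)
    }
  }
  design
}

#' Run an end-to-end screening analysis
#'
#' Simulates the configured panel (or analyzes supplied experiments),
#' computes each replicate's normalized deltaD trace and lysis call, and
#' compares the fixed-timepoint readouts of the phage-free arm (controls and
#' non-infectious exposures) against the infectious arm with a Welch
#' two-tailed t-test. Fully reproducible from (config, master seed). When
#' `config$output_dir` is set, a CSV report and overlay/readout plots are
#' written there.
#'
#' @param config A [screen_config()].
#' @param experiments Optional list of [qcmd_experiment()] objects to
#'   analyze instead of simulating (e.g. loaded via [read_trace()]).
#' @return An object of class `"screen_report"`: `table` (one row per
#'   experiment), `comparison` (a [group_compare()] result or NULL if an arm
#'   is too small), `series` (the normalized spread traces), `calls`,
#'   `config`, `config_hash`, `master_seed`.
#' @export
run_screen <- function(config, experiments = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(experiments)) {
    design <- build_design(config)
    if (length(design) == 0L) stop("empty panel", call. = FALSE)
    experiments <- simulate_panel(design, config$master_seed)
  }
  if (length(experiments) == 0L) stop("empty panel", call. = FALSE)
  an <- config$analysis
  calls <- vector("list", length(experiments))
  series <- vector("list", length(experiments))
  rows <- vector("list", length(experiments))
  for (i in seq_along(experiments)) {
    exp <- experiments[[i]]
    id <- sprintf("exp%02d", i)
    res <- tryCatch({
      inj <- phase_window(exp$schedule, "second_injection")
      ns <- normalize_spread(delta_d_spread(exp),
                             t_ref = unname(inj["start"]))
      call <- classify_lysis(ns, exp$schedule,
                             rule = an$rule %||% "mean_sign",
                             halfwidth = an$halfwidth %||% 5,
                             readout_time = an$readout_time %||% 240,
                             settling_buffer = an$settling_buffer %||% 10)
      list(ns = ns, call = call)
    }, error = function(e) {
      stop("screen stage failed for ", id, " (", exp$sensor_id, "): ",
           conditionMessage(e), call. = FALSE)
    })
    calls[[i]] <- res$call
    series[[i]] <- res$ns
    truth <- exp$label %||% NA_character_
    rows[[i]] <- data.frame(
      id = id, sensor_id = exp$sensor_id, truth = truth,
      call = res$call$label,
      drop_fraction = res$call$drop_fraction,
      readout = res$call$readout_240,
      derivative_sum = res$call$derivative_sum,
      derivative_mean = res$call$derivative_mean,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$truth_lytic <- ifelse(is.na(tab$truth), NA,
                            tab$truth == "infectious")
  minus <- tab$readout[!is.na(tab$truth_lytic) & !tab$truth_lytic]
  plus <- tab$readout[!is.na(tab$truth_lytic) & tab$truth_lytic]
  comparison <- if (length(minus) >= 2L && length(plus) >= 2L) {
    group_compare(minus, plus)
  } else NULL
  report <- structure(list(table = tab, comparison = comparison,
                           series = series, calls = calls, config = config,
                           config_hash = config_hash(config),
                           master_seed = config$master_seed,
                           version = as.character(utils::packageVersion("qcmdlysis"))),
                      class = "screen_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$output_dir, "report.csv"),
                     row.names = FALSE)
    grDevices::pdf(file.path(config$output_dir, "normalized_spread.pdf"),
                   width = 7, height = 5)
    plot(report, type = "overlay")
    grDevices::dev.off()
    grDevices::pdf(file.path(config$output_dir, "readout.pdf"),
                   width = 5, height = 5)
    plot(report, type = "readout")
    grDevices::dev.off()
  }
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("QCM-D lysis screen: ", nrow(x$table), " experiments (seed ",
      x$master_seed, ", config ", x$config_hash, ")\n", sep = "")
  print(x$table[, c("id", "truth", "call", "drop_fraction", "readout")],
        digits = 3)
  if (!is.null(x$comparison)) {
    cat("\nreadout comparison, -phage vs +phage:\n")
    print(x$comparison)
  }
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  tab <- object$table
  acc <- mean(tab$call == ifelse(tab$truth_lytic, "lytic", "non_lytic"),
              na.rm = TRUE)
  cat("experiments:", nrow(tab), "\n")
  if (!all(is.na(tab$truth_lytic))) {
    cat(sprintf("label recovery vs ground truth: %.1f%%\n", 100 * acc))
  }
  print(object)
  invisible(list(accuracy = acc, table = tab,
                 comparison = object$comparison))
}

#' Plot a screen report
#'
#' `type = "overlay"`: normalized deltaD traces, infectious arms in red,
#' phage-free arms in grey/blue, readout time marked. `type = "readout"`:
#' per-arm mean +/- SD of the fixed-timepoint readout.
#'
#' @param x A `"screen_report"`.
#' @param type `"overlay"` or `"readout"`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.screen_report <- function(x, type = c("overlay", "readout"), ...) {
  type <- match.arg(type)
  tab <- x$table
  cols <- ifelse(tab$truth == "infectious", "firebrick",
                 ifelse(tab$truth == "non_infectious", "steelblue", "grey30"))
  if (type == "overlay") {
    rng <- range(unlist(lapply(x$series, `[[`, "value")))
    plot(NA, xlim = range(x$series[[1L]]$time), ylim = rng,
         xlab = "time (min)", ylab = "normalized deltaD",
         main = "overtone spread, normalized to pre-injection maximum")
    for (i in seq_along(x$series)) {
      graphics::lines(x$series[[i]]$time, x$series[[i]]$value, col = cols[i])
    }
    rt <- x$config$analysis$readout_time %||% 240
    graphics::abline(v = rt, lty = 2, col = "grey50")
    graphics::legend("topleft",
                     legend = c("infectious", "non-infectious", "control"),
                     col = c("firebrick", "steelblue", "grey30"), lty = 1,
                     bty = "n", cex = 0.8)
  } else {
    arm <- ifelse(tab$truth_lytic, "+phage", "-phage")
    mns <- tapply(tab$readout, arm, mean)
    sds <- tapply(tab$readout, arm, stats::sd)
    bp <- graphics::barplot(mns, ylim = c(0, max(mns + sds, na.rm = TRUE) * 1.2),
                            ylab = "normalized deltaD at readout",
                            col = c("grey70", "firebrick"))
    graphics::arrows(bp, mns - sds, bp, mns + sds, angle = 90, code = 3,
                     length = 0.06)
    if (!is.null(x$comparison)) {
      graphics::mtext(paste0("Welch p = ",
                             signif(x$comparison$p_value, 2), " [",
                             x$comparison$stars, "]"), cex = 0.8)
    }
  }
  invisible(x)
}
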