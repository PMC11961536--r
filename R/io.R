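# QCMD-CSV dialect:
#   '#'-prefixed header lines carry key: value metadata (sensor_id,
#   fundamental_frequency_hz, overtones, optional label) and one
#   'phase:' line per schedule phase (name,start,end,medium,flow_rate);
#   then one CSV header row and columns time_min, df{n}_hz, dD{n}_e6 per
#   overtone. Floats are written with 17 significant digits so a
#   write/read cycle round-trips exactly.

#' Write an experiment to the QCMD-CSV dialect
#'
#' Deterministic output: fixed column order (ascending overtone, frequency
#' before dissipation), full-precision floats, schedule embedded in the
#' header. Writing the same experiment twice yields byte-identical files.
#'
#' @param exp A [qcmd_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(exp, path) {
  stopifnot(inherits(exp, "qcmd_experiment"))
  ns <- overtones(exp)
  g <- function(x) sprintf("%.17g", x)
  hdr <- c(
    "# qcmdlysis_trace_v1",
    paste0("# sensor_id: ", exp$sensor_id),
    paste0("# fundamental_frequency_hz: ", g(exp$fundamental_frequency)),
    paste0("# overtones: ", paste(ns, collapse = ",")),
    if (!is.null(exp$label)) paste0("# label: ", exp$label),
    vapply(seq_len(nrow(exp$schedule)), function(i) {
      r <- exp$schedule[i, ]
      paste0("# phase: ", r$name, ",", g(r$start), ",", g(r$end), ",",
             r$medium, ",", g(r$flow_rate))
    }, character(1))
  )
  cols <- c("time_min",
            as.vector(rbind(paste0("df", ns, "_hz"), paste0("dD", ns, "_e6"))))
  mat <- cbind(experiment_time(exp))
  for (n in ns) {
    mat <- cbind(mat, get_overtone_series(exp, n, "frequency"),
                 get_overtone_series(exp, n, "dissipation"))
  }
  rows <- apply(mat, 1L, function(r) paste(g(r), collapse = ","))
  writeLines(c(hdr, paste(cols, collapse = ","), rows), path)
  invisible(path)
}

#' Read an experiment from the QCMD-CSV dialect
#'
#' Parses the metadata header, the embedded phase schedule (overridable via
#' the `schedule` argument) and the trace columns, validating the result
#' against the full experiment invariants. Malformed input produces errors
#' that name the offending line or column.
#'
#' @param path File in the dialect written by [write_trace()].
#' @param schedule Optional [phase_schedule()] overriding the embedded one.
#' @return A [qcmd_experiment()].
#' @export
read_trace <- function(path, schedule = NULL) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta) - 1L
  if (is.na(n_meta)) n_meta <- length(lines)
  meta_lines <- lines[seq_len(n_meta)]

  meta <- list()
  phases <- list()
  for (i in seq_along(meta_lines)) {
    ln <- sub("^#\\s*", "", meta_lines[i])
    if (ln == "qcmdlysis_trace_v1" || ln == "") next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) {
      stop("malformed metadata at line ", i, ": '", meta_lines[i], "'",
           call. = FALSE)
    }
    if (m[2L] == "phase") {
      f <- strsplit(m[3L], ",", fixed = TRUE)[[1L]]
      if (length(f) != 5L) {
        stop("malformed phase metadata at line ", i, call. = FALSE)
      }
      phases[[length(phases) + 1L]] <- data.frame(
        name = f[1L], start = as.numeric(f[2L]), end = as.numeric(f[3L]),
        medium = f[4L], flow_rate = as.numeric(f[5L]),
        stringsAsFactors = FALSE)
    } else {
      meta[[m[2L]]] <- m[3L]
    }
  }
  if (is.null(meta$sensor_id) || is.null(meta$fundamental_frequency_hz)) {
    stop("malformed metadata: sensor_id and fundamental_frequency_hz headers ",
         "are required", call. = FALSE)
  }
  if (is.null(schedule)) {
    if (length(phases) == 0L) {
      stop("no schedule: file has no phase metadata and no schedule was ",
           "supplied", call. = FALSE)
    }
    schedule <- phase_schedule(do.call(rbind, phases))
  }

  body <- lines[-seq_len(n_meta)]
  if (length(body) < 3L) stop("no data rows in ", path, call. = FALSE)
  cols <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (cols[1L] != "time_min") {
    stop("first column must be time_min, found '", cols[1L], "'",
         call. = FALSE)
  }
  ns <- as.integer(strsplit(meta$overtones %||% "", ",")[[1L]])
  if (length(ns) == 0L || anyNA(ns)) {
    stop("malformed metadata: overtones header missing or unreadable",
         call. = FALSE)
  }
  want <- as.vector(rbind(paste0("df", ns, "_hz"), paste0("dD", ns, "_e6")))
  missing_cols <- setdiff(want, cols)
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- utils::read.csv(text = body, header = TRUE,
                         colClasses = "numeric", check.names = FALSE)
  if (any(diff(dat$time_min) <= 0)) {
    stop("non-monotone time: time_min must be strictly increasing",
         call. = FALSE)
  }
  traces <- lapply(ns, function(n) {
    overtone_trace(n, dat$time_min, dat[[paste0("df", n, "_hz")]],
                   dat[[paste0("dD", n, "_e6")]])
  })
  qcmd_experiment(traces, schedule, sensor_id = meta$sensor_id,
                  fundamental_frequency = as.numeric(meta$fundamental_frequency_hz),
                  label = meta$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
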