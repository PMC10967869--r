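# Process-log CSV round-trip and run segmentation.
#
# Schema (5 s cadence, header row, '.' decimal, comma-separated):
# timestamp_s, tmp_bar, q_per_lph, q_per_setpoint_lph, torque_nm, valve_pct,
# mode, status

PROCESS_LOG_COLUMNS <- c("timestamp_s", "tmp_bar", "q_per_lph",
                         "q_per_setpoint_lph", "torque_nm", "valve_pct",
                         "mode", "status")

#' Write / read a process log CSV
#'
#' Lossless round-trip of the plant's 5 s sensor/actuator time series.
#' `read_process_log()` validates the schema, reports malformed rows with
#' their line number and rejects non-monotone timestamps.
#'
#' @param log a process-log data.frame (e.g. `simulate_run(...)$log` or
#'   `plant$log()`).
#' @param path CSV file path.
#' @return `read_process_log()` returns the validated data.frame.
#' @export
write_process_log <- function(log, path) {
  missing_cols <- setdiff(PROCESS_LOG_COLUMNS, names(log))
  if (length(missing_cols))
    stop("write_process_log: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(log[PROCESS_LOG_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_process_log
#' @export
read_process_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PROCESS_LOG_COLUMNS, names(df))
  if (length(missing_cols))
    stop("read_process_log: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(PROCESS_LOG_COLUMNS, c("mode", "status"))
  for (nm in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[nm]]))))
    if (length(bad))
      stop(sprintf("read_process_log: malformed value in column '%s', line %d",
                   nm, bad[1] + 1L), call. = FALSE)
    df[[nm]] <- as.numeric(df[[nm]])
  }
  if (nrow(df) > 1) {
    # timestamps restart at run boundaries; within a status stretch they must
    # strictly increase
    run_id <- cumsum(c(TRUE, df$timestamp_s[-1] < df$timestamp_s[-nrow(df)] |
                         df$status[-1] != df$status[-nrow(df)]))
    for (g in split(seq_len(nrow(df)), run_id)) {
      ts <- df$timestamp_s[g]
      if (length(ts) > 1 && is.unsorted(ts, strictly = TRUE))
        stop("read_process_log: non-monotone timestamps around line ",
             g[which(diff(ts) <= 0)[1]] + 1L, call. = FALSE)
    }
  }
  df
}

#' Segment a continuous log into single filtration runs
#'
#' Automates the manual segmentation of the 24/7 plant log: splits on status
#' transitions (idle -> running -> idle), returning one data.frame per
#' running stretch.
#'
#' @param log a process-log data.frame.
#' @return list of process-log data.frames, one per run.
#' @export
segment_runs <- function(log) {
  if (!nrow(log)) return(list())
  running <- log$status == "running"
  edge <- c(running[1], diff(running) == 1)
  run_id <- cumsum(edge & running)
  run_id[!running] <- 0L
  out <- split(log, run_id)
  out[["0"]] <- NULL
  lapply(unname(out), function(d) { rownames(d) <- NULL; d })
}
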