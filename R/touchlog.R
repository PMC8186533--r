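TOUCHLOG_COLS <- c("subject_id", "group", "subtest_id", "item_id", "t", "x", "y", "phase")
PHASES <- c("press", "move", "release")

#' Write / read the touch-log CSV dialect
#'
#' One row per touch sample, header required, UTF-8, '.' decimal separator,
#' columns `subject_id, group, subtest_id, item_id, t, x, y, phase`.
#' Columns may appear in any order in a file being read; phases must be one
#' of `press`, `move`, `release`. Write then read round-trips losslessly.
#'
#' @param log touch-log `data.table`.
#' @param path CSV file path.
#' @export
write_touch_log <- function(log, path) {
  data.table::fwrite(log[, TOUCHLOG_COLS, with = FALSE], path)
  invisible(path)
}

#' @rdname write_touch_log
#' @return `read_touch_log()`: a touch-log `data.table` in canonical column
#'   order.
#' @export
read_touch_log <- function(path) {
  if (!file.exists(path)) tk_stop("touchkin_io_error", "touch log not found: %s", path)
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  missing <- setdiff(TOUCHLOG_COLS, header)
  if (length(missing)) {
    tk_stop("touchkin_io_error", "touch log missing column(s): %s",
            paste(missing, collapse = ", "))
  }
  log <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "group", "phase"),
    integer = c("subtest_id", "item_id"),
    numeric = c("t", "x", "y")
  ))
  data.table::setcolorder(log, TOUCHLOG_COLS)
  bad <- which(!log$phase %in% PHASES)
  if (length(bad)) {
    tk_stop("touchkin_io_error", "invalid phase '%s' at line %d of %s",
            log$phase[bad[1]], bad[1] + 1L, path)
  }
  if (anyNA(log$x) || anyNA(log$y) || anyNA(log$t)) {
    bad <- which(is.na(log$x) | is.na(log$y) | is.na(log$t))[1]
    tk_stop("touchkin_io_error", "non-numeric coordinate/time at line %d of %s",
            bad + 1L, path)
  }
  log[]
}
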