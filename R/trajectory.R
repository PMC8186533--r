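#' Segment one touch stream into finite trajectories
#'
#' A finite trajectory is the contiguous run of samples from a finger press
#' (first tap) up to and including the sample at which the finger is lifted
#' (release). Episodes shorter than `min_points` samples (default 2: a speed
#' needs two points) are dropped and counted in the discard log. Samples with
#' phase `move` falling outside any press-release episode are discarded with
#' a warning (device noise); a `release` with no open press is a
#' malformed-stream error naming the sample index.
#'
#' @param stream a single-stream touch-log `data.table` (one subject, one
#'   subtest, one item; `t` strictly increasing).
#' @param min_points minimum samples for an episode to be kept.
#' @return list of trajectories, each a `data.table` with columns
#'   `t, x, y` and attributes `subject_id`, `subtest_id`, `item_id`; the list
#'   carries attribute `discard` = `list(episodes, samples, orphan_moves)`
#'   counting dropped short episodes, their samples, and out-of-episode moves,
#'   so that kept points + discarded samples = samples inside episodes.
#' @export
segment_finite_trajectories <- function(stream, min_points = 2L) {
  if (is.unsorted(stream$t, strictly = TRUE)) {
    tk_stop("touchkin_stream_error", "stream timestamps are not strictly increasing")
  }
  phase <- stream$phase
  n <- length(phase)
  trajs <- list()
  discard_epi <- 0L
  discard_samp <- 0L
  orphan <- 0L
  open_start <- NA_integer_
  for (i in seq_len(n)) {
    p <- phase[i]
    if (p == "press") {
      if (!is.na(open_start)) {
        tk_stop("touchkin_stream_error",
                "press at sample %d while an episode is already open", i)
      }
      open_start <- i
    } else if (p == "release") {
      if (is.na(open_start)) {
        tk_stop("touchkin_stream_error", "release without matching press at sample %d", i)
      }
      len <- i - open_start + 1L
      if (len >= min_points) {
        tr <- stream[open_start:i, c("t", "x", "y")]
        data.table::setattr(tr, "subject_id", stream$subject_id[1])
        data.table::setattr(tr, "subtest_id", stream$subtest_id[1])
        data.table::setattr(tr, "item_id", stream$item_id[1])
        data.table::setattr(tr, "class", c("trajectory", class(tr)))
        trajs[[length(trajs) + 1L]] <- tr
      } else {
        discard_epi <- discard_epi + 1L
        discard_samp <- discard_samp + len
      }
      open_start <- NA_integer_
    } else if (is.na(open_start)) {
      orphan <- orphan + 1L
    }
  }
  if (orphan > 0) {
    tk_warn("touchkin_orphan_moves", "%d move sample(s) outside any press-release episode discarded", orphan)
  }
  structure(trajs,
            discard = list(episodes = discard_epi, samples = discard_samp,
                           orphan_moves = orphan))
}

#' Segment every stream of a stacked touch log
#'
#' @param log touch-log `data.table` (possibly many streams).
#' @inheritParams segment_finite_trajectories
#' @return flat list of trajectories with a combined `discard` attribute.
#' @export
segment_touch_log <- function(log, min_points = 2L) {
  out <- list()
  epi <- 0L; samp <- 0L; orph <- 0L
  for (stream in split_streams(log)) {
    tr <- segment_finite_trajectories(stream, min_points)
    d <- attr(tr, "discard")
    epi <- epi + d$episodes; samp <- samp + d$samples; orph <- orph + d$orphan_moves
    out <- c(out, tr)
  }
  structure(out, discard = list(episodes = epi, samples = samp, orphan_moves = orph))
}

#' Validate a trajectory's invariants
#'
#' Checks that a trajectory has at least 2 points, strictly increasing
#' timestamps and finite coordinates; returns it unchanged if so. Each
#' violation raises a distinct classed error
#' (`touchkin_short_trajectory`, `touchkin_timestamp_error`,
#' `touchkin_nonfinite_error`).
#'
#' @param traj a trajectory `data.table` (`t, x, y`).
#' @return `traj`, unchanged.
#' @export
validate_trajectory <- function(traj) {
  if (nrow(traj) < 2) {
    tk_stop("touchkin_short_trajectory", "trajectory has %d point(s); need >= 2", nrow(traj))
  }
  if (is.unsorted(traj$t, strictly = TRUE)) {
    tk_stop("touchkin_timestamp_error", "trajectory timestamps are not strictly increasing")
  }
  if (!all(is.finite(traj$x)) || !all(is.finite(traj$y)) || !all(is.finite(traj$t))) {
    tk_stop("touchkin_nonfinite_error", "trajectory contains non-finite coordinates")
  }
  traj
}

#' Export trajectories as a flat CSV with a trajectory_id column
#'
#' @param trajs list of trajectories (from [segment_touch_log()]).
#' @param path CSV path.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    data.table::data.table(
      trajectory_id = i, subject_id = attr(tr, "subject_id"),
      subtest_id = attr(tr, "subtest_id"), item_id = attr(tr, "item_id"),
      t = tr$t, x = tr$x, y = tr$y
    )
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}
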