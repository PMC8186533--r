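# Fixed column layout of the assembled learning problem.
KINEMATIC_FEATURES <- c(
  "MeanSpeed", "MaxSpeed", "MinSpeed", "sdSpeed",
  "MeanAcceleration", "MaxAcceleration", "MinAcceleration", "sdAcceleration",
  "STH", "DC", "sdDC", "MeanLength"
)

#' Names of the model's input columns
#'
#' @return `kinematic_feature_names()`: the 12 kinematic feature names in
#'   fixed order. `feature_columns()`: all 17 input columns (12 kinematic +
#'   5 subtest indicators FG, FC, CA, SO, VP).
#' @export
kinematic_feature_names <- function() KINEMATIC_FEATURES

#' @rdname kinematic_feature_names
#' @export
feature_columns <- function() c(KINEMATIC_FEATURES, subtest_codes())

#' Per-step kinematics of a trajectory
#'
#' Discrete forward-difference kinematics over the n points of a trajectory:
#' \deqn{speed_i = \|p_{i+1} - p_i\| / (t_{i+1} - t_i)}
#' \deqn{accel_i = (speed_{i+1} - speed_i) / (t_{i+1} - t_i)}
#' \deqn{DC_i = |wrap(heading_{i+1} - heading_i)| / (t_{i+1} - t_i)}
#' with headings from `atan2` of each displacement, angle differences wrapped
#' to (-pi, pi], and acceleration the signed derivative of scalar speed.
#' Zero-length steps contribute speed 0 and propagate the previous heading
#' (leading zero-length steps take the first defined heading, or 0 if the
#' trajectory never moves).
#'
#' @param traj trajectory `data.table` with >= 2 points.
#' @return list with `speed` (length n-1), `acceleration` (n-2), `heading`
#'   (n-1), `dc` (n-2), `path_length`, `net_displacement`.
#' @export
step_kinematics <- function(traj) {
  validate_trajectory(traj)
  dt <- diff(traj$t)
  if (any(dt <= 0)) tk_stop("touchkin_timestamp_error", "duplicate or decreasing timestamps")
  dx <- diff(traj$x); dy <- diff(traj$y)
  d <- sqrt(dx^2 + dy^2)
  speed <- d / dt
  heading <- atan2(dy, dx)
  zero <- d == 0
  if (any(zero)) {
    # propagate last defined heading across zero-length steps
    hval <- heading; hval[zero] <- NA_real_
    for (i in seq_along(hval)) {
      if (is.na(hval[i])) hval[i] <- if (i > 1) hval[i - 1] else NA_real_
    }
    if (is.na(hval[1])) {
      first_def <- which(!is.na(hval))[1]
      fill <- if (is.na(first_def)) 0 else hval[first_def]
      hval[is.na(hval)] <- fill
    }
    heading <- hval
  }
  n_step <- length(speed)
  accel <- if (n_step >= 2) diff(speed) / dt[-n_step] else numeric(0)
  dc <- if (n_step >= 2) abs(wrap_angle(diff(heading))) / dt[-n_step] else numeric(0)
  list(speed = speed, acceleration = accel, heading = heading, dc = dc,
       path_length = sum(d),
       net_displacement = sqrt((traj$x[nrow(traj)] - traj$x[1])^2 +
                               (traj$y[nrow(traj)] - traj$y[1])^2))
}

#' Straightness index of a trajectory
#'
#' Ratio of the distance between the start and end points to the path
#' length; 1 for a straight monotone path, 0 for a closed loop. A
#' zero-length path has no defined straightness and returns `NA`.
#'
#' @param traj trajectory `data.table`.
#' @return value in \[0, 1\], or `NA_real_` if the path length is 0.
#' @export
straightness_index <- function(traj) {
  k <- step_kinematics(traj)
  if (k$path_length == 0) return(NA_real_)
  k$net_displacement / k$path_length
}

#' Mean and SD of directional change
#'
#' Directional change is the absolute change in heading between successive
#' displacement vectors per unit time (radians/s), with angle differences
#' wrapped to (-pi, pi]. Needs at least 3 points; otherwise both statistics
#' are `NA` (undefined, not zero -- zero-filling would bias DC downward).
#'
#' @param traj trajectory `data.table`.
#' @return named vector `c(mean_dc, sd_dc)` in radians/s; `sd_dc` is the
#'   sample SD (NA when only one DC step exists).
#' @export
directional_change_stats <- function(traj) {
  if (nrow(traj) < 3) return(c(mean_dc = NA_real_, sd_dc = NA_real_))
  dc <- step_kinematics(traj)$dc
  c(mean_dc = mean(dc), sd_dc = if (length(dc) >= 2) sample_sd(dc) else NA_real_)
}

#' Aggregate one task's trajectories into a feature vector
#'
#' Per-task aggregation of the 12 kinematic features. Features are first
#' computed per finite trajectory and then averaged over the task's
#' trajectories:
#' * `MeanSpeed`, `MeanAcceleration`, `DC`: mean over trajectories of each
#'   trajectory's mean (this, rather than pooling steps, keeps
#'   `MinSpeed <= MeanSpeed <= MaxSpeed` on every row);
#' * `sdSpeed`, `sdAcceleration`, `sdDC`: sample SD over all steps pooled
#'   across the task (the spread of the values collected during the task);
#' * `MaxSpeed`, `MinSpeed`, `MaxAcceleration`, `MinAcceleration`: mean over
#'   trajectories of each trajectory's extremum (the "average peak");
#' * `STH`: mean of per-trajectory straightness;
#' * `MeanLength`: mean per-trajectory path length (the per-task trajectory
#'   count is returned as the auxiliary diagnostic `n_trajectories`, not a
#'   model input).
#' Trajectories whose series are undefined for a feature (e.g. 2-point bouts
#' have no acceleration or DC) are excluded from that feature's aggregate.
#'
#' @param trajectories list of trajectories of one (subject, task).
#' @param subtest_id integer 1-5.
#' @param item_id integer 1-5.
#' @param label `"ASD"` or `"TD"`.
#' @param subject_id subject identifier.
#' @return one-row `data.table`: 12 kinematic features, 5 subtest indicator
#'   columns, `label`, `subject_id`, `subtest_id`, `item_id`,
#'   `n_trajectories`; or `NULL` (with a message) if no trajectory yields
#'   defined features.
#' @export
featurize_task <- function(trajectories, subtest_id, item_id = NA_integer_,
                           label, subject_id = NA_character_) {
  if (length(trajectories) == 0) {
    message(sprintf("task skipped (subject %s, subtest %s): no trajectories",
                    subject_id, subtest_id))
    return(NULL)
  }
  kin <- lapply(trajectories, step_kinematics)
  speeds <- unlist(lapply(kin, `[[`, "speed"))
  accels <- unlist(lapply(kin, `[[`, "acceleration"))
  dcs <- unlist(lapply(kin, `[[`, "dc"))
  if (length(speeds) == 0) {
    message(sprintf("task skipped (subject %s, subtest %s): no defined steps",
                    subject_id, subtest_id))
    return(NULL)
  }
  per_traj <- function(field, f) {
    v <- vapply(kin, function(k) if (length(k[[field]])) f(k[[field]]) else NA_real_, 0)
    mean(v, na.rm = TRUE)
  }
  sth_each <- vapply(seq_along(kin), function(i) {
    if (kin[[i]]$path_length == 0) NA_real_ else kin[[i]]$net_displacement / kin[[i]]$path_length
  }, 0)
  lens <- vapply(kin, `[[`, 0, "path_length")

  row <- data.table::data.table(
    MeanSpeed = per_traj("speed", mean),
    MaxSpeed = per_traj("speed", max),
    MinSpeed = per_traj("speed", min),
    sdSpeed = if (length(speeds) >= 2) sample_sd(speeds) else NA_real_,
    MeanAcceleration = if (length(accels)) per_traj("acceleration", mean) else NA_real_,
    MaxAcceleration = per_traj("acceleration", max),
    MinAcceleration = per_traj("acceleration", min),
    sdAcceleration = if (length(accels) >= 2) sample_sd(accels) else NA_real_,
    STH = mean(sth_each, na.rm = TRUE),
    DC = if (length(dcs)) per_traj("dc", mean) else NA_real_,
    sdDC = if (length(dcs) >= 2) sample_sd(dcs) else NA_real_,
    MeanLength = mean(lens)
  )
  for (j in seq_along(subtest_codes())) {
    row[[subtest_codes()[j]]] <- as.integer(j == subtest_id)
  }
  row$label <- label
  row$subject_id <- subject_id
  row$subtest_id <- as.integer(subtest_id)
  row$item_id <- as.integer(item_id)
  row$n_trajectories <- length(trajectories)
  row
}

#' Build the feature table from a touch log
#'
#' Segments every stream of the log into finite trajectories and aggregates
#' each (subject, task) into one row; the default cohort design yields
#' 60 x 25 = 1,500 rows of 17 input features plus label and identifiers.
#'
#' @param log touch-log `data.table`.
#' @param min_points segmentation threshold, see
#'   [segment_finite_trajectories()].
#' @return a `feature_table` `data.table` in fixed column order:
#'   12 kinematic features, 5 indicators, `label`, `subject_id`,
#'   `subtest_id`, `item_id`, `n_trajectories`.
#' @export
featurize_cohort <- function(log, min_points = 2L) {
  rows <- list()
  for (stream in split_streams(log)) {
    trajs <- suppressWarnings(segment_finite_trajectories(stream, min_points))
    row <- featurize_task(trajs, subtest_id = stream$subtest_id[1],
                          item_id = stream$item_id[1],
                          label = stream$group[1],
                          subject_id = stream$subject_id[1])
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  assemble_dataset(rows)
}

#' Assemble task feature vectors into one table
#'
#' @param vectors list of one-row tables from [featurize_task()].
#' @return a `feature_table` with fixed column order; errors if a subject
#'   appears with conflicting labels.
#' @export
assemble_dataset <- function(vectors) {
  vectors <- vectors[!vapply(vectors, is.null, TRUE)]
  if (length(vectors) == 0) tk_stop("touchkin_feature_error", "no feature vectors to assemble")
  tab <- data.table::rbindlist(vectors)
  lab_per_subj <- tapply(tab$label, tab$subject_id, function(l) length(unique(l)))
  if (any(lab_per_subj > 1)) {
    tk_stop("touchkin_label_error", "conflicting labels for subject(s): %s",
            paste(names(lab_per_subj)[lab_per_subj > 1], collapse = ", "))
  }
  if (anyNA(tab[, feature_columns(), with = FALSE])) {
    tk_stop("touchkin_feature_error", "missing values in assembled feature table")
  }
  data.table::setcolorder(tab, c(feature_columns(), "label", "subject_id",
                                 "subtest_id", "item_id", "n_trajectories"))
  data.table::setattr(tab, "class", c("feature_table", class(tab)))
  tab[]
}

#' Standardize the kinematic feature columns
#'
#' Centers and scales the 12 kinematic columns to zero mean and unit sample
#' SD (n - 1 denominator). Indicator, label and identifier columns are left
#' untouched. With `params = "fit"` the scaler is fitted on the table;
#' passing a previously fitted `scaler_params` applies it to held-out data.
#'
#' @param table a `feature_table`.
#' @param params `"fit"` or a `scaler_params` object.
#' @return list with `table` (standardized copy) and `params`
#'   (`scaler_params`: per-feature `mean` and `sd`).
#' @export
standardize <- function(table, params = "fit") {
  feats <- KINEMATIC_FEATURES
  if (identical(params, "fit")) {
    mu <- vapply(feats, function(f) mean(table[[f]]), 0)
    sig <- vapply(feats, function(f) sample_sd(table[[f]]), 0)
    if (any(!is.finite(sig)) || any(sig <= 0)) {
      tk_stop("touchkin_constant_column",
              "constant or degenerate feature column(s): %s",
              paste(feats[!is.finite(sig) | sig <= 0], collapse = ", "))
    }
    params <- structure(list(mean = mu, sd = sig), class = "scaler_params")
  } else if (!inherits(params, "scaler_params")) {
    tk_stop("touchkin_config_error", "params must be \"fit\" or a scaler_params object")
  }
  out <- data.table::copy(table)
  for (f in feats) {
    data.table::set(out, j = f, value = (out[[f]] - params$mean[[f]]) / params$sd[[f]])
  }
  list(table = out, params = params)
}

#' Serialize / restore scaler parameters as a key-value text file
#'
#' @param params a `scaler_params` object.
#' @param path text file path.
#' @export
write_scaler <- function(params, path) {
  kv <- c(setNames(as.list(params$mean), paste0("mean.", names(params$mean))),
          setNames(as.list(params$sd), paste0("sd.", names(params$sd))))
  write_config(kv, path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  kv <- read_config(path)
  feats <- KINEMATIC_FEATURES
  mu <- unlist(kv[paste0("mean.", feats)]); names(mu) <- feats
  sig <- unlist(kv[paste0("sd.", feats)]); names(sig) <- feats
  structure(list(mean = mu, sd = sig), class = "scaler_params")
}

#' Write the feature table as CSV
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- data.table::fread(path, colClasses = list(character = c("label", "subject_id")))
  data.table::setattr(tab, "class", c("feature_table", class(tab)))
  tab[]
}
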