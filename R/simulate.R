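#' Task specifications
#'
#' A task is one item of one of the five subtests (FG, FC, CA, SO, VP). The
#' on-screen layout is a start zone (where the draggable cards sit) and a
#' goal zone (where they must be dropped) on a 1280 x 800 screen, with the
#' touch stream sampled at 40 Hz. By default item `i` requires `i` cards to
#' be dragged (1 to 5).
#'
#' @param subtest_id integer 1-5.
#' @param item_id integer 1-5.
#' @param n_drags number of cards to drag (1-5); default `item_id`.
#' @param start_zone,goal_zone named numeric rectangles
#'   (`xmin`, `ymin`, `xmax`, `ymax`) in screen units, inside the screen.
#' @param screen `c(width, height)` in screen units.
#' @param sample_rate sampling rate in Hz.
#' @return a `task_spec` list.
#' @export
task_spec <- function(subtest_id, item_id, n_drags = item_id,
                      start_zone = c(xmin = 80, ymin = 620, xmax = 360, ymax = 760),
                      goal_zone = c(xmin = 920, ymin = 60, xmax = 1200, ymax = 240),
                      screen = c(width = 1280, height = 800),
                      sample_rate = 40) {
  if (sample_rate <= 0) tk_stop("touchkin_config_error", "sample_rate must be > 0")
  if (n_drags < 1 || n_drags > 5) tk_stop("touchkin_config_error", "n_drags must be in [1, 5]")
  for (z in list(start_zone, goal_zone)) {
    if (z[["xmin"]] < 0 || z[["ymin"]] < 0 ||
        z[["xmax"]] > screen[["width"]] || z[["ymax"]] > screen[["height"]]) {
      tk_stop("touchkin_config_error", "zone lies outside the screen")
    }
  }
  structure(list(subtest_id = as.integer(subtest_id), item_id = as.integer(item_id),
                 n_drags = as.integer(n_drags), start_zone = start_zone,
                 goal_zone = goal_zone, screen = screen, sample_rate = sample_rate),
            class = "task_spec")
}

#' Default task roster: 5 subtests x 5 items
#'
#' @param sample_rate sampling rate passed to every [task_spec()].
#' @return list of 25 `task_spec` objects.
#' @export
default_task_roster <- function(sample_rate = 40) {
  roster <- list()
  for (s in 1:5) for (i in 1:5) {
    roster[[length(roster) + 1L]] <- task_spec(s, i, sample_rate = sample_rate)
  }
  roster
}

#' @export
subtest_codes <- function() c("FG", "FC", "CA", "SO", "VP")

#' Draw a subject's latent motor profile
#'
#' Latent parameters are drawn independently from the group's normal
#' distributions and truncated to their valid ranges (e.g. `goal_gain` to
#' \[0, 1\], rates to non-negative values).
#'
#' @param group `"ASD"` or `"TD"`.
#' @param effect_config a [group_effect_preset()] result, preset name, or
#'   equivalent list.
#' @param seed integer seed; same seed, same profile.
#' @return a `subject_profile` list of the six latent parameters.
#' @export
sample_subject_profile <- function(group, effect_config, seed) {
  if (!group %in% c("ASD", "TD")) {
    tk_stop("touchkin_config_error", "unknown group label '%s'", group)
  }
  cfg <- resolve_effect_config(effect_config)[[group]]
  set.seed(seed)
  pars <- latent_param_names()
  ranges <- latent_param_ranges()
  draw <- rnorm(length(pars), mean = cfg$mean[pars], sd = cfg$sd[pars])
  names(draw) <- pars
  for (p in pars) draw[[p]] <- min(max(draw[[p]], ranges[[p]][1]), ranges[[p]][2])
  structure(c(as.list(draw), list(group = group)), class = "subject_profile")
}

#' Simulate one subject-task touch stream
#'
#' The motion model is a goal-attracted correlated walk. At each 1/40 s step
#' the heading is the angle of
#' `goal_gain * u(bearing-to-goal) + (1 - goal_gain) * u(previous heading)`
#' (with `u()` the unit vector) plus Gaussian jitter of SD
#' `heading_noise_sd`; the step length is `speed / sample_rate` where speed
#' follows a smooth bell profile scaled by `base_speed`, multiplied by
#' lognormal noise with coefficient of variation `speed_cv`, plus
#' acceleration bursts `N(0, accel_burst_sd) * dt`. Finger lifts occur as a
#' Poisson process with mean `fragmentation_rate` lifts per drag; each lift
#' emits a release sample and restarts with a press at the next tick. Each
#' drag runs from a random point in the start zone until the touch point
#' enters the goal zone.
#'
#' @param profile a [sample_subject_profile()] result.
#' @param spec a [task_spec()].
#' @param seed integer seed.
#' @param subject_id identifier stamped on every sample.
#' @param step_cap maximum steps per drag before a runaway-parameter error.
#' @return a `data.table` with columns `subject_id`, `group`, `subtest_id`,
#'   `item_id`, `t`, `x`, `y`, `phase` (`press`/`move`/`release`), `t`
#'   strictly increasing at 1/`sample_rate` spacing.
#' @export
generate_task_stream <- function(profile, spec, seed, subject_id = "S1",
                                 step_cap = 4000L) {
  if (spec$sample_rate <= 0) tk_stop("touchkin_config_error", "sample_rate must be > 0")
  set.seed(seed)
  dt <- 1 / spec$sample_rate
  sdlog <- sqrt(log(1 + profile$speed_cv^2))
  goal <- rect_center(spec$goal_zone)
  scr_w <- spec$screen[["width"]]; scr_h <- spec$screen[["height"]]

  t_cur <- 0
  ts <- xs <- ys <- numeric(0)
  ph <- character(0)
  emit <- function(x, y, phase) {
    ts[length(ts) + 1L] <<- t_cur
    xs[length(xs) + 1L] <<- x
    ys[length(ys) + 1L] <<- y
    ph[length(ph) + 1L] <<- phase
    t_cur <<- t_cur + dt
  }

  for (drag in seq_len(spec$n_drags)) {
    x <- runif(1, spec$start_zone[["xmin"]], spec$start_zone[["xmax"]])
    y <- runif(1, spec$start_zone[["ymin"]], spec$start_zone[["ymax"]])
    d0 <- sqrt((goal[["x"]] - x)^2 + (goal[["y"]] - y)^2)
    heading <- atan2(goal[["y"]] - y, goal[["x"]] - x)
    # expected drag duration for the bell speed profile (mean of sin lobe ~ 0.64)
    expected_T <- d0 / (0.64 * profile$base_speed)
    n_lifts <- rpois(1, profile$fragmentation_rate)
    lift_frac <- if (n_lifts > 0) sort(runif(n_lifts, 0.05, 0.95)) else numeric(0)
    lifts_done <- 0L

    emit(x, y, "press")
    elapsed <- 0
    step <- 0L
    repeat {
      step <- step + 1L
      if (step > step_cap) {
        tk_stop("touchkin_runaway_error",
                "goal not reached within %d steps (subject %s, subtest %d item %d)",
                step_cap, subject_id, spec$subtest_id, spec$item_id)
      }
      bell <- 0.15 + 0.85 * sin(pi * min(elapsed / expected_T, 1))
      bell <- max(bell, 0.15)
      speed <- profile$base_speed * bell * rlnorm(1, -sdlog^2 / 2, sdlog) +
        rnorm(1, 0, profile$accel_burst_sd) * dt
      speed <- max(speed, 0.02 * profile$base_speed)
      bearing <- atan2(goal[["y"]] - y, goal[["x"]] - x)
      vx <- profile$goal_gain * cos(bearing) + (1 - profile$goal_gain) * cos(heading)
      vy <- profile$goal_gain * sin(bearing) + (1 - profile$goal_gain) * sin(heading)
      heading <- atan2(vy, vx)
      if (profile$heading_noise_sd > 0) heading <- heading + rnorm(1, 0, profile$heading_noise_sd)
      x <- min(max(x + speed * dt * cos(heading), 0), scr_w)
      y <- min(max(y + speed * dt * sin(heading), 0), scr_h)
      elapsed <- elapsed + dt

      if (point_in_rect(x, y, spec$goal_zone)) {
        emit(x, y, "release")
        break
      }
      progress <- 1 - sqrt((goal[["x"]] - x)^2 + (goal[["y"]] - y)^2) / d0
      if (lifts_done < n_lifts && progress >= lift_frac[lifts_done + 1L]) {
        lifts_done <- lifts_done + 1L
        emit(x, y, "release")
        # finger re-touches close to where it lifted
        x <- min(max(x + rnorm(1, 0, 3), 0), scr_w)
        y <- min(max(y + rnorm(1, 0, 3), 0), scr_h)
        emit(x, y, "press")
      } else {
        emit(x, y, "move")
      }
    }
  }

  data.table::data.table(
    subject_id = subject_id, group = profile$group,
    subtest_id = spec$subtest_id, item_id = spec$item_id,
    t = ts, x = xs, y = ys, phase = ph
  )
}

#' Generate a full synthetic cohort of touch streams
#'
#' One touch stream per subject per task. The default design mirrors the
#' study: 30 subjects per group, 5 subtests x 5 items, 40 Hz on a
#' 1280 x 800 screen, i.e. 1,500 streams. A single master seed is fanned out
#' to per-subject and per-task seeds via [derive_seed()], so identical
#' `(config, seed)` give byte-identical cohorts.
#'
#' @param n_per_group subjects per group (>= 1).
#' @param effect_config preset name or [group_effect_preset()] result.
#' @param roster list of [task_spec()]s; default [default_task_roster()].
#' @param seed master integer seed.
#' @return a `data.table` touch log (all streams stacked, one row per touch
#'   sample) with attribute `profiles` holding each subject's latent profile.
#' @export
generate_cohort <- function(n_per_group = 30, effect_config = "default",
                            roster = default_task_roster(), seed = 1) {
  if (n_per_group < 1) tk_stop("touchkin_config_error", "n_per_group must be >= 1")
  if (length(roster) == 0) tk_stop("touchkin_config_error", "task roster is empty")
  effect_config <- resolve_effect_config(effect_config)
  groups <- rep(c("ASD", "TD"), each = n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "ASD", "A", "T"),
                 c(seq_len(n_per_group), seq_len(n_per_group)))
  profiles <- list()
  chunks <- vector("list", length(ids) * length(roster))
  k <- 0L
  for (i in seq_along(ids)) {
    prof <- sample_subject_profile(groups[i], effect_config,
                                   derive_seed(seed, "profile", ids[i]))
    profiles[[ids[i]]] <- prof
    for (ts in roster) {
      k <- k + 1L
      chunks[[k]] <- generate_task_stream(
        prof, ts, derive_seed(seed, "stream", ids[i], ts$subtest_id, ts$item_id),
        subject_id = ids[i]
      )
    }
  }
  log <- data.table::rbindlist(chunks)
  data.table::setattr(log, "profiles", profiles)
  log
}

#' Split a stacked touch log into per-stream tables
#'
#' @param log a touch log `data.table` as produced by [generate_cohort()].
#' @return named list of per-(subject, subtest, item) `data.table`s.
#' @export
split_streams <- function(log) {
  key <- paste(log$subject_id, log$subtest_id, log$item_id, sep = "|")
  split(log, factor(key, levels = unique(key)))
}
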