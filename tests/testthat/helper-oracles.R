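# Independent brute-force oracles: naive point-by-point loops, written
# without reference to the package's vectorized implementations.

oracle_wrap <- function(a) {
  while (a > pi) a <- a - 2 * pi
  while (a <= -pi) a <- a + 2 * pi
  a
}

# All per-trajectory quantities by explicit loops over points.
oracle_trajectory <- function(t, x, y) {
  n <- length(t)
  speed <- numeric(0); heading <- numeric(0)
  path <- 0
  for (i in seq_len(n - 1)) {
    d <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    path <- path + d
    speed <- c(speed, d / (t[i + 1] - t[i]))
    h <- if (d == 0) {
      if (length(heading)) heading[length(heading)] else NA_real_
    } else {
      atan2(y[i + 1] - y[i], x[i + 1] - x[i])
    }
    heading <- c(heading, h)
  }
  # leading zero-length steps inherit the first defined heading (0 if none)
  if (length(heading) && is.na(heading[1])) {
    def <- heading[!is.na(heading)]
    heading[is.na(heading)] <- if (length(def)) def[1] else 0
  }
  accel <- numeric(0); dc <- numeric(0)
  for (i in seq_len(max(n - 2, 0))) {
    accel <- c(accel, (speed[i + 1] - speed[i]) / (t[i + 1] - t[i]))
    dc <- c(dc, abs(oracle_wrap(heading[i + 1] - heading[i])) / (t[i + 1] - t[i]))
  }
  net <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  list(speed = speed, acceleration = accel, heading = heading, dc = dc,
       path_length = path, net_displacement = net,
       straightness = if (path > 0) net / path else NA_real_)
}

# Per-task aggregation by explicit loops over trajectories.
oracle_featurize <- function(traj_list) {
  ks <- lapply(traj_list, function(tr) oracle_trajectory(tr$t, tr$x, tr$y))
  pool_speed <- unlist(lapply(ks, `[[`, "speed"))
  pool_acc <- unlist(lapply(ks, `[[`, "acceleration"))
  pool_dc <- unlist(lapply(ks, `[[`, "dc"))
  mean_of <- function(f, field) {
    v <- sapply(ks, function(k) if (length(k[[field]])) f(k[[field]]) else NA_real_)
    mean(v, na.rm = TRUE)
  }
  c(MeanSpeed = mean_of(mean, "speed"),
    MaxSpeed = mean_of(max, "speed"),
    MinSpeed = mean_of(min, "speed"),
    sdSpeed = sd(pool_speed),
    MeanAcceleration = mean_of(mean, "acceleration"),
    MaxAcceleration = mean_of(max, "acceleration"),
    MinAcceleration = mean_of(min, "acceleration"),
    sdAcceleration = sd(pool_acc),
    STH = mean(sapply(ks, `[[`, "straightness"), na.rm = TRUE),
    DC = mean_of(mean, "dc"),
    sdDC = sd(pool_dc),
    MeanLength = mean(sapply(ks, `[[`, "path_length")))
}

# Random micro-trajectory with >= 3 points at irregular positive time steps.
random_micro_trajectory <- function(n = NULL) {
  n <- n %||% sample(3:8, 1)
  data.table::data.table(
    t = cumsum(runif(n, 0.01, 0.1)),
    x = cumsum(rnorm(n, sd = 2)),
    y = cumsum(rnorm(n, sd = 2))
  )
}

make_traj <- function(t, x, y) data.table::data.table(t = t, x = x, y = y)

# Tiny touch stream assembled by hand: phases given explicitly.
make_stream <- function(phases, t = seq_along(phases) * 0.025,
                        x = seq_along(phases), y = rep(0, length(phases))) {
  data.table::data.table(subject_id = "S1", group = "TD", subtest_id = 1L,
                         item_id = 1L, t = t, x = x, y = y, phase = phases)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small balanced feature table with planted separation in chosen columns:
# label = ASD when the informative column is positive. Noise columns are
# standard normal.
toy_feature_table <- function(n = 120, informative = "MeanSpeed", seed = 1,
                              duplicate_of = NULL) {
  set.seed(seed)
  feats <- touchkin::kinematic_feature_names()
  tab <- data.table::as.data.table(
    setNames(lapply(feats, function(f) rnorm(n)), feats)
  )
  lab <- ifelse(tab[[informative]] > 0, "ASD", "TD")
  if (!is.null(duplicate_of)) tab[[duplicate_of[2]]] <- tab[[duplicate_of[1]]]
  for (j in seq_along(touchkin::subtest_codes())) {
    tab[[touchkin::subtest_codes()[j]]] <- as.integer(((seq_len(n) - 1) %% 5 + 1) == j)
  }
  tab$label <- lab
  tab$subject_id <- sprintf("S%03d", seq_len(n))
  tab$subtest_id <- (seq_len(n) - 1L) %% 5L + 1L
  tab$item_id <- 1L
  tab$n_trajectories <- 1L
  data.table::setattr(tab, "class", c("feature_table", class(tab)))
  tab[]
}

# Small planted-signal cohort used by several suites (kept small for speed).
small_cohort_table <- function(seed = 1, n_per_group = 6, preset = "default") {
  roster <- list()
  for (s in 1:5) for (i in 1:2) roster[[length(roster) + 1L]] <- touchkin::task_spec(s, i)
  log <- touchkin::generate_cohort(n_per_group, preset, roster, seed = seed)
  touchkin::featurize_cohort(log)
}
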