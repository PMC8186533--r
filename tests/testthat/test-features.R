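test_that("hand-computed kinematics match", {
  # unit steps at 40 Hz: 1 unit / 0.025 s = 40 units/s
  tr <- make_traj(c(0, 0.025, 0.05), c(0, 1, 2), c(0, 0, 0))
  k <- step_kinematics(tr)
  expect_equal(k$speed, c(40, 40))
  expect_equal(k$acceleration, 0)
  expect_equal(k$dc, 0)

  # 3-4-5 step: 5 units / 0.025 s
  expect_equal(step_kinematics(make_traj(c(0, 0.025), c(0, 3), c(0, 4)))$speed, 200)

  # stationary step: speed 0, heading propagated
  k2 <- step_kinematics(make_traj(c(0, 0.025, 0.05), c(0, 1, 1), c(0, 0, 0)))
  expect_equal(k2$speed, c(40, 0))
  expect_equal(k2$heading, c(0, 0))

  # straightness of an L-shaped path: sqrt(2) / 2
  L <- make_traj(c(0, 0.025, 0.05), c(0, 1, 1), c(0, 0, 1))
  expect_equal(straightness_index(L), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(straightness_index(make_traj(c(0, 0.025), c(0, 5), c(0, 0))), 1)
  # closed loop
  sq <- make_traj((0:4) * 0.025, c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(straightness_index(sq), 0)
  # zero path length -> undefined marker, not an error
  expect_true(is.na(straightness_index(make_traj(c(0, 0.025), c(1, 1), c(2, 2)))))

  # 90 degree turn at 40 Hz: (pi/2) / 0.025
  dc <- directional_change_stats(L)
  expect_equal(unname(dc["mean_dc"]), (pi / 2) / 0.025, tolerance = 1e-12)
  # 180 degree reversal: pi / 0.025, the wrap ceiling
  rev <- make_traj(c(0, 0.025, 0.05), c(0, 1, 0), c(0, 0, 0))
  expect_equal(step_kinematics(rev)$dc, pi / 0.025, tolerance = 1e-12)
  expect_true(all(step_kinematics(rev)$dc <= pi / 0.025 + 1e-9))
  # < 3 points -> undefined
  expect_true(all(is.na(directional_change_stats(make_traj(c(0, 0.025), 0:1, c(0, 0))))))
  expect_error(step_kinematics(make_traj(c(0, 0, 0.05), 0:2, c(0, 0, 0))),
               class = "touchkin_timestamp_error")
})

test_that("all features match the brute-force oracle on random trajectories", {
  set.seed(42)
  for (i in 1:300) {
    tr <- random_micro_trajectory()
    k <- step_kinematics(tr)
    o <- oracle_trajectory(tr$t, tr$x, tr$y)
    expect_equal(k$speed, o$speed, tolerance = 1e-9)
    expect_equal(k$acceleration, o$acceleration, tolerance = 1e-9)
    expect_equal(k$dc, o$dc, tolerance = 1e-9)
    expect_equal(k$path_length, o$path_length, tolerance = 1e-9)
    expect_equal(straightness_index(tr), o$straightness, tolerance = 1e-9)
  }
  # per-task aggregation against the oracle aggregator
  for (i in 1:50) {
    trajs <- lapply(seq_len(sample(2:4, 1)), function(j) random_micro_trajectory())
    row <- featurize_task(trajs, subtest_id = 1, label = "TD")
    o <- oracle_featurize(trajs)
    expect_equal(unlist(row[, kinematic_feature_names(), with = FALSE]), o,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("scale and time equivariance hold", {
  set.seed(7)
  for (i in 1:20) {
    tr <- random_micro_trajectory(6)
    c1 <- runif(1, 0.5, 3)
    scaled <- make_traj(tr$t, tr$x * c1, tr$y * c1)
    k <- step_kinematics(tr); ks <- step_kinematics(scaled)
    expect_equal(ks$speed, k$speed * c1, tolerance = 1e-9)
    expect_equal(ks$acceleration, k$acceleration * c1, tolerance = 1e-9)
    expect_equal(ks$path_length, k$path_length * c1, tolerance = 1e-9)
    expect_equal(ks$dc, k$dc, tolerance = 1e-9)
    expect_equal(straightness_index(scaled), straightness_index(tr), tolerance = 1e-9)

    c2 <- runif(1, 0.5, 3)
    slowed <- make_traj(tr$t * c2, tr$x, tr$y)
    kt <- step_kinematics(slowed)
    expect_equal(kt$speed, k$speed / c2, tolerance = 1e-9)
    expect_equal(kt$acceleration, k$acceleration / c2^2, tolerance = 1e-9)
    expect_equal(kt$dc, k$dc / c2, tolerance = 1e-9)
    expect_equal(kt$path_length, k$path_length, tolerance = 1e-9)
  }
})

test_that("featurize_task aggregates and degenerates as documented", {
  straight <- make_traj((0:4) * 0.025, 0:4, rep(0, 5))
  row <- featurize_task(list(straight), subtest_id = 3, label = "ASD", subject_id = "A01")
  expect_equal(row$MeanSpeed, row$MaxSpeed)
  expect_equal(row$MeanSpeed, row$MinSpeed)
  expect_equal(row$sdSpeed, 0)
  expect_equal(row$STH, 1)
  expect_equal(row$DC, 0)
  expect_equal(row$sdDC, 0)
  expect_equal(row$MeanLength, 4)
  expect_identical(unlist(row[, subtest_codes(), with = FALSE]),
                   c(FG = 0L, FC = 0L, CA = 1L, SO = 0L, VP = 0L))
  expect_identical(length(kinematic_feature_names()), 12L)

  two <- featurize_task(list(make_traj((0:2) * 0.025, c(0, 1, 2), c(0, 0, 0)),
                             make_traj((0:2) * 0.025, c(0, 2, 4), c(0, 0, 0))),
                        subtest_id = 1, label = "TD")
  expect_equal(two$MeanLength, 3)
  expect_identical(two$n_trajectories, 2L)

  expect_null(suppressMessages(featurize_task(list(), 1, label = "TD")))
})

test_that("ordering invariants hold on every emitted row", {
  tab <- small_cohort_table(seed = 31, n_per_group = 4)
  expect_true(all(tab$MinSpeed <= tab$MeanSpeed + 1e-9))
  expect_true(all(tab$MeanSpeed <= tab$MaxSpeed + 1e-9))
  expect_true(all(tab$MinAcceleration <= tab$MeanAcceleration + 1e-9))
  expect_true(all(tab$MeanAcceleration <= tab$MaxAcceleration + 1e-9))
  expect_true(all(tab$STH > 0 & tab$STH <= 1))
  expect_true(all(rowSums(tab[, subtest_codes(), with = FALSE]) == 1))
})

test_that("assemble_dataset enforces schema and label consistency", {
  set.seed(99)
  r1 <- featurize_task(list(random_micro_trajectory(5)), 1, 1, "ASD", "S1")
  r2 <- featurize_task(list(random_micro_trajectory(5)), 2, 1, "TD", "S2")
  tab <- assemble_dataset(list(r1, r2))
  expect_identical(names(tab)[1:17], feature_columns())
  expect_identical(nrow(tab), 2L)

  r3 <- featurize_task(list(random_micro_trajectory(5)), 2, 1, "TD", "S1")
  expect_error(assemble_dataset(list(r1, r3)), class = "touchkin_label_error")
})

test_that("standardization matches its definition and round-trips", {
  tab <- toy_feature_table(n = 60, seed = 5)
  tab$MeanSpeed <- c(1, 2, 3, rep(2, 57)) # known column: mean 2
  std <- standardize(tab, "fit")
  for (f in kinematic_feature_names()) {
    expect_equal(mean(std$table[[f]]), 0, tolerance = 1e-12)
    expect_equal(sd(std$table[[f]]), 1, tolerance = 1e-12)
  }
  # {1,2,3} -> {-1,0,1} under mean 2, sample SD 1
  x <- c(1, 2, 3)
  expect_equal((x - mean(x)) / sd(x), c(-1, 0, 1))
  expect_equal(unname(std$params$mean[["MeanSpeed"]]), 2)

  # applying fitted params to held-out rows uses the stored moments
  held <- toy_feature_table(n = 10, seed = 6)
  reapplied <- standardize(held, std$params)$table
  expect_equal(reapplied$MaxSpeed,
               (held$MaxSpeed - std$params$mean[["MaxSpeed"]]) / std$params$sd[["MaxSpeed"]])

  cons <- toy_feature_table(n = 20, seed = 7)
  cons$DC <- 1
  expect_error(standardize(cons, "fit"), class = "touchkin_constant_column")

  p <- withr::local_tempfile(fileext = ".txt")
  write_scaler(std$params, p)
  back <- read_scaler(p)
  expect_equal(back$mean, std$params$mean, tolerance = 1e-12)
  expect_equal(back$sd, std$params$sd, tolerance = 1e-12)
})
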