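test_that("metrics match hand calculations on a piecewise trace", {
  dt <- 0.1
  t <- seq(0, 10, by = dt)
  # pedestrian walks at 1.2 m/s from 3 m out; driver decelerates from 12 m/s
  # at exactly the rate required to stop at its conflict entry (40 m)
  ped_d <- 3 - 1.2 * t
  ped_v <- rep(1.2, length(t))
  a <- 12^2 / (2 * 40)
  tstop <- 12 / a
  drv_v <- pmax(12 - a * t, 0)
  drv_d <- ifelse(t < tstop, 40 - (12 * t - 0.5 * a * t^2), 0)
  tr <- synthetic_trace(t, ped_d, ped_v, drv_d, drv_v,
                        drv_a = ifelse(t < tstop, -a, 0))
  m <- compute_metrics(tr)

  # entry at d <= -0.05: first step past the line
  t_entry <- t[which(ped_d <= -0.05)[1]]
  expect_equal(m$ped_entry_time, t_entry)
  expect_equal(m$ped_speed_ratio, 1.2 / 1.5)
  expect_equal(m$veh_speed_at_ped_crossing, drv_v[t == t_entry])
  # exact-required deceleration: zero excess (on the analytic profile the
  # identity v^2 / (2 d) = a holds at every step)
  expect_lt(abs(m$mean_excess_decel), 1e-9)
  expect_equal(m$outcome, "ped_first")
  expect_false(m$collision)
})

test_that("a constant-speed pedestrian at its free speed has ratio one", {
  t <- seq(0, 5, by = 0.1)
  tr <- synthetic_trace(t, 4.5 - 1.5 * t, rep(1.5, length(t)),
                        1e5 - 13.4 * t, rep(13.4, length(t)))
  m <- compute_metrics(tr)
  expect_equal(m$ped_speed_ratio, 1)
})

test_that("collision and non-progression follow the context rules", {
  t <- seq(0, 21, by = 0.1)
  # agents entering 5 s apart: no collision
  tr <- synthetic_trace(t, 8 - 1.5 * t, rep(1.5, length(t)),
                        170 - 13.4 * t, rep(13.4, length(t)))
  cn <- detect_collision_nonprogression(tr, context = "exp2")
  expect_false(cn$collision)
  # pedestrian enters at 19.9 s, driver at 12 s: both within 20 s
  tr2 <- synthetic_trace(t, 1.5 * (19.92 - t), rep(1.5, length(t)),
                         13.4 * (12 - t), rep(13.4, length(t)))
  cn2 <- detect_collision_nonprogression(tr2, context = "exp2")
  expect_false(cn2$nonprogression)
  # driver never enters within 20 s: non-progression
  tr3 <- synthetic_trace(t, 1.5 * (3 - t), rep(1.5, length(t)),
                         13.4 * (25 - t), rep(13.4, length(t)))
  expect_true(detect_collision_nonprogression(tr3, context = "exp2")$nonprogression)
  # simultaneous occupancy is a collision
  tr4 <- synthetic_trace(t, 1.5 * (3 - t), rep(1.5, length(t)),
                         13.4 * (3 - t), rep(13.4, length(t)))
  expect_true(detect_collision_nonprogression(tr4, context = "exp2")$collision)
})

test_that("the two-vehicle experiment exclusion rule detects stuck pedestrians", {
  t <- seq(0, 20, by = 0.1)
  # car fully stopped, pedestrian never crosses
  tr <- synthetic_trace(t, rep(1, length(t)), rep(0, length(t)),
                        pmax(30 - 10 * t, 2.5), pmax(10 - 10 * t, 0))
  expect_true(detect_collision_nonprogression(tr, context = "exp1")$nonprogression)
  # pedestrian crosses: no exclusion
  tr2 <- synthetic_trace(t, 1 - 1.2 * t, rep(1.2, length(t)),
                         pmax(30 - 10 * t, 2.5), pmax(10 - 10 * t, 0))
  expect_false(detect_collision_nonprogression(tr2, context = "exp1")$nonprogression)
})

test_that("phenomenon flags apply the defining inequalities inclusively", {
  mk <- function(...) {
    m <- list(ped_speed_ratio = NA, veh_speed_ratio = NA,
              veh_speed_at_ped_crossing = NA, mean_excess_decel = NA,
              final_stop_distance = NA)
    modifyList(m, list(...))
  }
  crit <- retention_criteria()
  # strict inequality: a vehicle exactly at standstill is not early yield
  expect_false(phenomenon_flag(list(mk(veh_speed_at_ped_crossing = 0)),
                               "early_yield_acceptance", crit))
  expect_true(phenomenon_flag(list(mk(veh_speed_at_ped_crossing = 2)),
                              "early_yield_acceptance", crit))
  # positive excess deceleration without a substantial stopping distance
  # does not count as short-stopping
  expect_false(phenomenon_flag(list(mk(mean_excess_decel = 0.4,
                                       final_stop_distance = 0.2)),
                               "short_stopping", crit))
  expect_true(phenomenon_flag(list(mk(mean_excess_decel = 0.4,
                                      final_stop_distance = 1.8)),
                              "short_stopping", crit))
  # any kinematic variant suffices
  reports <- list(mk(ped_speed_ratio = 1), mk(ped_speed_ratio = 0.9))
  expect_true(phenomenon_flag(reports, "gap_acceptance_hesitation", crit))
  # loosening criteria never turns a true flag false
  crit2 <- retention_criteria(hesitation_ratio = 0.999)
  for (r in list(0.9, 0.95, 1.01)) {
    f1 <- phenomenon_flag(list(mk(ped_speed_ratio = r)),
                          "yield_acceptance_hesitation", crit)
    f2 <- phenomenon_flag(list(mk(ped_speed_ratio = r)),
                          "yield_acceptance_hesitation", crit2)
    expect_true(f2 >= f1)
  }
})
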