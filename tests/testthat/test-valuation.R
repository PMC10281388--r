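test_that("kinematic reward has the calibrated quadratic shape", {
  rp <- default_reward_params("pedestrian")
  expect_equal(kinematic_reward(0, 0, rp), 0)
  expect_equal(kinematic_reward(rp$v_free, 0, rp), rp$k_dv * rp$v_free^2)
  # symmetric about the free speed for a = 0
  expect_equal(kinematic_reward(rp$v_free + 0.4, 0, rp),
               kinematic_reward(rp$v_free - 0.4, 0, rp))
})

test_that("squash is an odd sigmoid onto [-1, 1]", {
  expect_equal(squash(0, 1), 0)
  expect_equal(squash(Inf, 1), 1)
  expect_equal(squash(-Inf, 1), -1)
  u <- seq(-5, 5, by = 0.7)
  expect_equal(squash(-u, 0.3), -squash(u, 0.3))
  expect_true(all(abs(squash(u * 100, 1)) <= 1))
  expect_equal(squash(-Inf, 1, "arctan"), -1)
  expect_equal(squash(1, 1, "arctan"), (2 / pi) * atan(pi / 2))
})

test_that("state prediction is exact for closed-form cases", {
  # no pending primitives, null action, constant speeds: uniform motion
  es <- ego_state("pedestrian", dist = 5, speed = 1.2)
  ps <- predict_state(es, 0, other_d = 40, other_v = 10, other_accel = 0,
                      horizon = 0.5)
  expect_equal(ps$ego_d, 5 - 1.2 * 0.5)
  expect_equal(ps$ego_v, 1.2)
  expect_equal(ps$other_d, 40 - 10 * 0.5)

  # driver at 10 m/s with a +1 m/s^2 action: closed form vs fine integration
  es2 <- ego_state("driver", dist = 100, speed = 10, ctrl_now = 0,
                   ramp_dur = 0.4)
  ps2 <- predict_state(es2, 1, other_d = 1e6, other_v = 0, horizon = 0.5)
  # closed form: accel ramps linearly to 1 m/s^2 over 0.4 s, then holds
  v_exact <- 10 + 0.5 * 0.4 + 0.1          # 10.3
  adv <- (10 * 0.4 + 0.4^3 / (3 * 0.8)) +  # ramp phase (v = 10 + t^2/0.8)
    (10.2 * 0.1 + 0.5 * 1 * 0.1^2)         # constant-accel phase
  expect_lt(abs(ps2$ego_v - v_exact), 1e-9)
  expect_lt(abs(ps2$ego_d - (100 - adv)), 1e-9)

  # a pending primitive half-way through its ramp is part of the prediction
  es3 <- ego_state("pedestrian", dist = 5, speed = 1.2, ctrl_now = 1.2,
                   ramp_rem = 0.2, ramp_amp = 0.5, ramp_dur = 0.4)
  ps3 <- predict_state(es3, 0, other_d = 1e6, other_v = 0, horizon = 0.5)
  # speed rises by the remaining half of the ramp
  expect_equal(ps3$ego_v, 1.2 + 0.5 * 0.5)
  # position advance: ramp slope 1.25 m/s^2 for 0.2 s then hold
  adv <- 1.2 * 0.2 + 0.5 * 1.25 * 0.2^2 + (1.2 + 0.25) * 0.3
  expect_equal(ps3$ego_d, 5 - adv, tolerance = 1e-9)

  # the other agent's speed clamps at zero under deceleration
  ps4 <- predict_state(es, 0, other_d = 40, other_v = 1, other_accel = -4,
                       horizon = 1)
  expect_equal(ps4$other_v, 0)
  expect_equal(ps4$other_d, 40 - 1^2 / (2 * 4))
})

test_that("short-term payoff prices collision courses and priority deficits", {
  rw <- default_reward_params("pedestrian")
  cfg <- valuation_config("short_term", role = "pedestrian",
                          collision_cost = 2, priority_cost = 2)
  # a lone agent at its free speed earns the maximum kinematics reward
  es <- ego_state("pedestrian", dist = 5, speed = 1.5)
  u_lone <- short_term_value(es, 0, other_d = 1e6, other_v = 0,
                             "pass_first", cfg, rw)
  expect_equal(u_lone, rw$k_dv * rw$v_free^2, tolerance = 1e-9)
  # pedestrian 2 s of walking from the conflict space, car 2 s away:
  # maintaining is on a collision course, slowing is not
  es2 <- ego_state("pedestrian", dist = 3, speed = 1.5)
  u_keep <- short_term_value(es2, 0, other_d = 2 * 13.4, other_v = 13.4,
                             "pass_first", cfg, rw)
  u_stop <- short_term_value(es2, -1.5, other_d = 2 * 13.4, other_v = 13.4,
                             "pass_first", cfg, rw)
  expect_lt(u_keep, u_stop)

  # driver exactly at the deceleration required to stop: no priority cost
  rwd <- default_reward_params("driver")
  dreq <- 10^2 / (2 * 30)
  mk <- function(pcost) {
    valuation_config("short_term", role = "driver", priority_cost = pcost,
                     oth_has_priority = TRUE)
  }
  # chosen so the predicted state at the horizon is exactly (d = 30, v = 10)
  esd <- ego_state("driver", dist = 30 + 10 * 0.5 + 0.125 * dreq,
                   speed = 10 + dreq * 0.5, ctrl_now = -dreq)
  u0 <- short_term_value(esd, 0, other_d = 1.5, other_v = 0, "pass_second",
                         mk(0), rwd)
  u5 <- short_term_value(esd, 0, other_d = 1.5, other_v = 0, "pass_second",
                         mk(5), rwd)
  expect_equal(u0, u5, tolerance = 1e-6)
})

test_that("access-order plans respect the other agent's occupancy", {
  rw <- default_reward_params("driver")
  cfg <- valuation_config("affordance", role = "driver")
  # other already past its exit: pass-first plan keeps the current profile
  es <- ego_state("driver", dist = 40, speed = 13.4)
  p <- plan_access_order(es, 0, other_d = -10, other_v = 1.4, "pass_first",
                         "pass_first", cfg, rw)
  expect_true(p$feasible)
  expect_equal(p$t_entry, 40 / 13.4, tolerance = 1e-6)

  # driver 3 s from entry; pedestrian entering in ~1 s, clearing in ~4 s:
  # the pass-second plan arrives no earlier than the pedestrian's exit
  es2 <- ego_state("driver", dist = 3 * 13.4, speed = 13.4)
  proj <- behavior_projection("pedestrian", assert_accel = 0, v_free = 1,
                              a_stop_max = 2)
  p2 <- plan_access_order(es2, 0, other_d = 1, other_v = 1, "pass_first",
                          "pass_second", cfg, rw, proj = proj)
  expect_true(p2$feasible)
  expect_gte(p2$t_entry, p2$other_t_exit - 1e-6)

  # kinematically impossible orders return the boundary plan, not an error
  es3 <- ego_state("driver", dist = 8, speed = 13.4)
  p3 <- plan_access_order(es3, 0, other_d = 0.5, other_v = 1.4, "pass_first",
                          "pass_second", cfg, rw, proj = proj)
  expect_false(p3$feasible)
})

test_that("affordance values integrate discounted reward with a steady tail", {
  rw <- default_reward_params("pedestrian")
  cfg <- valuation_config("affordance", role = "pedestrian", discount_T = 10)
  es <- ego_state("pedestrian", dist = 5, speed = 1.5)
  av <- affordance_value(es, 0, other_d = 1e6, other_v = 0, "pass_first",
                         cfg, rw)
  # closed-form limit: K(v_free) * discount_T
  expect_lt(abs(av$u - rw$k_dv * rw$v_free^2 * 10) / (10 * rw$k_dv * rw$v_free^2),
            0.01)
  # unobstructed: passing first is never worth less than passing second
  expect_gte(av$u_pass_first, av$u_pass_second - 1e-9)

  # the priority cost is additive on the pass-first order
  rwd <- default_reward_params("driver")
  esd <- ego_state("driver", dist = 40, speed = 13.4)
  base <- valuation_config("affordance", role = "driver", priority_cost = 2,
                           oth_has_priority = FALSE)
  prio <- valuation_config("affordance", role = "driver", priority_cost = 2,
                           oth_has_priority = TRUE)
  u0 <- affordance_value(esd, 0, other_d = 1.5, other_v = 0, "pass_second",
                         base, rwd)
  u1 <- affordance_value(esd, 0, other_d = 1.5, other_v = 0, "pass_second",
                         prio, rwd)
  expect_equal(u1$u_pass_first, u0$u_pass_first - 2, tolerance = 1e-9)
})

test_that("squashed values stay within [-1, 1] along full simulations", {
  sp <- build_phenomenon_scenarios()[["yield_acceptance_hesitation/tta+0.0"]]
  v <- model_variant("affordance", value_estimation = TRUE,
                     action_sensitive = TRUE)
  tr <- run_single_agent(sp, v, seed = 1)
  ped <- tr[tr$role == "pedestrian", ]
  ok <- is.finite(ped$Vhat_null)
  expect_true(all(abs(ped$Vhat_null[ok]) <= 1))
  expect_true(all(abs(ped$Vhat_best[ok]) <= 1))
})

test_that("sensory noise transforms into low-skewed value noise for maintaining", {
  # pedestrian mid-approach facing a marginally acceptable constant-speed
  # gap: the 20-80 band of the maintain-speed action value reaches farther
  # below its median than above (risk asymmetry)
  rw <- default_reward_params("pedestrian")
  cfg <- valuation_config("affordance", role = "pedestrian", discount_T = 10,
                          collision_cost = 30)
  es <- ego_state("pedestrian", dist = 3, speed = 1.5)
  b <- kalman_belief(c(66.6, 13.4), matrix(c(64, 2, 2, 2.25), 2, 2))
  set.seed(5)
  vals <- replicate(500, {
    p <- draw_percept(b, kinematic_state(3, 1.5))
    u1 <- affordance_value(es, 0, p$other_position, p$other_speed,
                           "pass_first", cfg, rw)$u
    u2 <- affordance_value(es, 0, p$other_position, p$other_speed,
                           "pass_second", cfg, rw)$u
    0.5 * squash(u1, cfg$squash_scale) + 0.5 * squash(u2, cfg$squash_scale)
  })
  q <- quantile(vals, c(0.2, 0.5, 0.8))
  expect_gt(q[2] - q[1], q[3] - q[2])
})
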