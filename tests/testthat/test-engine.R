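test_that("traces have the contracted shape and are reproducible", {
  sp <- lone_scenario("pedestrian", dist = 8, speed = 0, duration = 5)
  v <- model_variant("affordance", sensory_noise = "constant", kalman = TRUE,
                     accumulation = TRUE)
  tr1 <- run_single_agent(sp, v, seed = 42)
  tr2 <- run_single_agent(sp, v, seed = 42)
  expect_identical(tr1, tr2)
  ped <- tr1[tr1$role == "pedestrian", ]
  expect_equal(nrow(ped), 5 / 0.1 + 1)
  expect_true(all(diff(ped$t) > 0))
  # a different seed changes a stochastic run
  tr3 <- run_single_agent(sp, v, seed = 43)
  expect_false(identical(tr1$percept_pos, tr3$percept_pos))
})

test_that("deterministic variants are seed-independent", {
  sp <- build_phenomenon_scenarios()[["yield_acceptance_hesitation/tta+0.0"]]
  v <- model_variant("affordance", value_estimation = TRUE,
                     action_sensitive = TRUE)
  tr1 <- run_single_agent(sp, v, seed = 1)
  tr2 <- run_single_agent(sp, v, seed = 999)
  expect_identical(tr1$v, tr2$v)
})

test_that("per-subsystem random streams are independent", {
  a <- engine_stream_normals(7, 0, 0, 100)
  b <- engine_stream_normals(7, 0, 1, 100)
  c1 <- engine_stream_normals(7, 1, 0, 100)
  expect_identical(a, engine_stream_normals(7, 0, 0, 100))
  expect_gt(max(abs(a - b)), 0.1)
  expect_gt(max(abs(a - c1)), 0.1)
  # draws are standard normal to Monte-Carlo accuracy
  z <- engine_stream_normals(12, 0, 2, 2e4)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1), 0.02)
})

test_that("an unobstructed modeled agent crosses at its free speed", {
  sp <- lone_scenario("pedestrian", dist = 10, speed = 0)
  tr <- run_single_agent(sp, model_variant("affordance"), seed = 1)
  ped <- tr[tr$role == "pedestrian", ]
  expect_true(any(ped$d < -zone_length(conflict_geometry(), "pedestrian")))
  expect_lt(abs(tail(ped$v, 1) - 1.5), 0.08)
})

test_that("engine control bookkeeping matches the superposition formula", {
  sp <- lone_scenario("pedestrian", dist = 10, speed = 0, duration = 6)
  tr <- run_single_agent(sp, model_variant("affordance"), seed = 1)
  ped <- tr[tr$role == "pedestrian", ]
  amps <- ped$action
  amps[is.na(amps)] <- 0
  h <- control_history(amps, baseline_control = 0, dt = 0.1)
  prim <- motor_primitive(0.4)
  for (k in c(5, 12, 30, 59)) {
    # trace row k + 1 holds the control at step k + 1 of the superposition
    expect_equal(ped$control[k + 1],
                 control_signal(h, prim, k + 1, role = "driver"),
                 tolerance = 1e-9)
  }
})

test_that("engine decisions replicate the module-level pipeline", {
  # deterministic affordance agent without behavior estimation: each step is
  # P = (1/2, 1/2); V~_a = mean over behaviors of squashed affordance values;
  # no accumulation; threshold-gated argmax selection
  sp <- lone_scenario("pedestrian", dist = 4.5, speed = 1.5, duration = 1,
                      dt = 0.1)
  sp$initial_states$driver <- kinematic_state(80.4, 13.4)
  sp$scripts$driver <- script_profile("constant_speed", v0 = 13.4)
  v <- model_variant("affordance")
  tr <- run_single_agent(sp, v, seed = 1)
  ped <- tr[tr$role == "pedestrian", ]
  drv <- tr[tr$role == "driver", ]

  p <- default_params("pedestrian")
  rw <- default_reward_params("pedestrian")
  cfg <- valuation_config("affordance", role = "pedestrian",
                          discount_T = p$discount_T, collision_cost = 30,
                          priority_cost = p$priority_cost,
                          entry_margin = p$entry_margin)
  amps <- default_action_set("pedestrian")$amplitude
  state <- list(d = 4.5, v = 1.5, ctrl = 1.5, ramps = list())
  for (k in 1:3) {
    rem <- vapply(state$ramps, function(r) 0.4 - (0.1 * (k - 1) - r$t0),
                  numeric(1))
    keep <- rem > 1e-9
    es <- ego_state("pedestrian", state$d, state$v, ctrl_now = state$ctrl,
                    ramp_rem = rem[keep],
                    ramp_amp = vapply(state$ramps[keep], `[[`, numeric(1),
                                      "amp"),
                    ramp_dur = 0.4)
    od <- drv$d[k]
    ov <- drv$v[k]
    Vt <- vapply(amps, function(a) {
      u1 <- affordance_value(es, a, od, ov, "pass_first", cfg, rw)$u
      u2 <- affordance_value(es, a, od, ov, "pass_second", cfg, rw)$u
      0.5 * squash(u1, cfg$squash_scale) + 0.5 * squash(u2, cfg$squash_scale)
    }, numeric(1))
    acc <- accumulator(5, T = 0.1, sigma_V = 0, delta_V_th = p$delta_V_th,
                       null_index = 3, V_hat = Vt)
    sel <- select_action(acc, amps)
    expect_equal(ped$action[k], amps[sel])
    expect_equal(ped$Vhat_null[k], Vt[3], tolerance = 1e-9)
    if (sel != 3) {
      state$ramps <- c(state$ramps, list(list(t0 = 0.1 * (k - 1),
                                              amp = amps[sel])))
    }
    # advance kinematics exactly as the engine does
    tnext <- 0.1 * k
    ctrl_new <- 1.5
    for (r in state$ramps) {
      ctrl_new <- ctrl_new + r$amp * min(1, (tnext - r$t0) / 0.4)
    }
    vnew <- max(0, ctrl_new)
    state$d <- state$d - 0.1 * (state$v + vnew) / 2
    state$v <- vnew
    state$ctrl <- ctrl_new
    expect_equal(ped$d[k + 1], state$d, tolerance = 1e-9)
    expect_equal(ped$v[k + 1], state$v, tolerance = 1e-9)
  }
})

test_that("two-agent runs are synchronous and reproducible", {
  enc <- build_encounter_scenarios()
  v <- variant_max_successful()
  p <- list(sigma_s = 1, T = 0.4)
  tr1 <- run_two_agents(enc$encounter_no_priority, v, p, p, seed = 5)
  tr2 <- run_two_agents(enc$encounter_no_priority, v, p, p, seed = 5)
  expect_identical(tr1, tr2)
  n <- enc$encounter_no_priority$duration / enc$encounter_no_priority$dt + 1
  expect_equal(nrow(tr1), 2 * n)
  expect_error(run_two_agents(lone_scenario(), v), "both roles")
  expect_error(run_single_agent(enc$encounter_no_priority,
                                model_variant("affordance")),
               "exactly one")
})

test_that("agents with non-overlapping occupancy ignore each other's params", {
  # the pedestrian is long gone before the vehicle arrives
  sp <- scenario_spec(
    modeled_roles = c("pedestrian", "driver"),
    initial_states = list(pedestrian = kinematic_state(1, 1.5),
                          driver = kinematic_state(600, 13.4)),
    scripts = list(), duration = 10, dt = 0.1)
  v <- model_variant("affordance")
  tr1 <- run_two_agents(sp, v, list(), list(priority_cost = 1), seed = 1)
  tr2 <- run_two_agents(sp, v, list(), list(priority_cost = 19), seed = 1)
  p1 <- tr1[tr1$role == "pedestrian", ]
  p2 <- tr2[tr2$role == "pedestrian", ]
  expect_identical(p1$v, p2$v)
})
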