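test_that("phenomenon factory yields 5 phenomena x 3 TTA variants", {
  specs <- build_phenomenon_scenarios()
  expect_length(specs, 15)
  phens <- vapply(specs, function(s) s$phenomenon, character(1))
  expect_equal(sort(unique(table(phens))), 3, ignore_attr = TRUE)
  offs <- vapply(specs, function(s) s$tta_offset, numeric(1))
  expect_setequal(unique(offs), c(-0.5, 0, 0.5))
  # one-agent screens by construction
  expect_true(all(vapply(specs, function(s) length(s$modeled_roles) == 1,
                         logical(1))))
  # scripted vehicle initial distance = v0 * (base TTA + offset)
  sp <- specs[["gap_acceptance_hesitation/tta+0.5"]]
  expect_equal(sp$initial_states$driver$dist_to_conflict, 13.4 * 6)
  sp <- specs[["priority_assertion/tta-0.5"]]
  expect_equal(sp$initial_states$driver$dist_to_conflict, 13.4 * 2.5)
  # driver-modeled specs assert pedestrian priority
  expect_true(specs[["short_stopping/tta+0.0"]]$ped_priority)
  expect_false(specs[["gap_acceptance_hesitation/tta+0.0"]]$ped_priority)
})

test_that("encounter factory places both agents 3 s from the conflict space", {
  enc <- build_encounter_scenarios()
  expect_length(enc, 3)
  expect_true(all(vapply(enc, function(s) {
    setequal(s$modeled_roles, c("pedestrian", "driver"))
  }, logical(1))))
  for (nm in c("encounter_no_priority", "encounter_priority")) {
    s <- enc[[nm]]
    expect_equal(s$initial_states$pedestrian$dist_to_conflict, 3 * 1.5)
    expect_equal(s$initial_states$driver$dist_to_conflict, 3 * 13.4)
  }
  expect_equal(sum(vapply(enc[2:3], function(s) s$ped_priority, logical(1))), 1)
})

test_that("two-vehicle experiment factory matches the 3x4x2 design", {
  specs <- build_exp1_scenarios()
  expect_length(specs, 24)
  meta <- do.call(rbind, lapply(specs, function(s) {
    data.frame(speed = s$meta$speed, gap = s$meta$gap,
               yielding = s$meta$yielding)
  }))
  expect_equal(nrow(unique(meta)), 24)
  expect_setequal(unique(meta$speed), c(11.2, 13.4, 15.6))
  expect_setequal(unique(meta$gap), 2:5)
  # yielding script: implied deceleration over the 38.5 - 2.5 = 36 m interval
  sp <- specs[["exp1/v11.2/gap2/yield"]]
  pr <- sp$scripts$driver
  a <- pr$v0^2 / (2 * (pr$decel_start_dist - pr$decel_end_dist))
  expect_equal(a, 11.2^2 / (2 * 36))
  # constant-speed script: same speed at t = 0 and t = duration
  spc <- specs[["exp1/v11.2/gap2/const"]]
  st0 <- scripted_state(spc, "driver", 0)
  st1 <- scripted_state(spc, "driver", spc$duration)
  expect_equal(st0$speed, st1$speed)
  # pedestrian at standstill 1 m out; lead 3 s from completely passing
  expect_equal(sp$initial_states$pedestrian$dist_to_conflict, 1)
  expect_equal(sp$initial_states$pedestrian$speed, 0)
  zone <- zone_length(sp$geometry, "driver")
  expect_equal((sp$lead$state$dist_to_conflict + zone) / 11.2, 3)
})

test_that("interactive experiment factory matches the 5x2 design", {
  specs <- build_exp2_scenarios()
  expect_length(specs, 10)
  g3 <- specs[["exp2/gap3/plain"]]
  expect_equal(g3$initial_states$driver$dist_to_conflict, 13.4 * 2)
  expect_equal(g3$initial_states$driver$speed, 13.4)
  for (s in specs) {
    expect_equal(s$initial_states$pedestrian$dist_to_conflict, 1.95)
    expect_equal(s$initial_states$pedestrian$speed, 0)
    expect_equal(s$geometry$lane_width, 4.5)
  }
  expect_equal(sum(vapply(specs, function(s) s$ped_priority, logical(1))), 5)
})

test_that("scripted kinematics follow the closed-form profiles", {
  specs <- build_phenomenon_scenarios()
  sp <- specs[["gap_acceptance_hesitation/tta+0.0"]]
  # uniform motion: d = d0 - v t, TTA = d / v at every step
  tt <- seq(0, 5, by = 0.1)
  st <- scripted_state(sp, "driver", tt)
  d0 <- sp$initial_states$driver$dist_to_conflict
  expect_equal(st$dist_to_conflict, d0 - 13.4 * tt)
  expect_equal(st$dist_to_conflict / st$speed, d0 / 13.4 - tt)

  spy <- specs[["yield_acceptance_hesitation/tta+0.0"]]
  # deceleration switches on when the vehicle reaches the start distance
  pr <- spy$scripts$driver
  d0y <- spy$initial_states$driver$dist_to_conflict
  t_at <- (d0y - pr$decel_start_dist) / pr$v0
  before <- scripted_state(spy, "driver", t_at - 0.01)
  after <- scripted_state(spy, "driver", t_at + 0.01)
  expect_equal(before$accel, 0)
  expect_lt(after$accel, 0)
  # standstill at the end distance for large t
  late <- scripted_state(spy, "driver", 100)
  expect_equal(late$speed, 0)
  expect_equal(late$dist_to_conflict, pr$decel_end_dist)
  # continuity: no position jumps beyond v dt + |a| dt^2 / 2
  tt <- seq(0, 12, by = 0.05)
  st <- scripted_state(spy, "driver", tt)
  jumps <- abs(diff(st$dist_to_conflict))
  bound <- head(st$speed, -1) * 0.05 + 0.5 * 13.4 * 0.05^2
  expect_true(all(jumps <= bound + 1e-9))
})

test_that("predefined speed series integrates exactly", {
  pr <- script_profile("predefined_series", v0 = 2,
                       series_t = c(0, 1, 3), series_v = c(2, 0, 4))
  sp <- scenario_spec(
    modeled_roles = "driver",
    initial_states = list(pedestrian = kinematic_state(10, 2),
                          driver = kinematic_state(100, 13.4)),
    scripts = list(pedestrian = pr), duration = 5, dt = 0.1)
  st <- scripted_state(sp, "pedestrian", c(0.5, 1, 2, 3, 4))
  # trapezoid areas: linear speed makes them exact
  expect_equal(st$speed, c(1, 0, 2, 4, 4))
  expect_equal(st$dist_to_conflict,
               10 - c(0.75, 1, 2, 5, 9))
})

test_that("querying a modeled role as scripted is an error", {
  sp <- lone_scenario("pedestrian")
  expect_error(scripted_state(sp, "pedestrian", 1), "modeled")
})

test_that("scenario factories are deterministic and serialize round-trip", {
  expect_identical(build_phenomenon_scenarios(), build_phenomenon_scenarios())
  expect_identical(build_exp1_scenarios(), build_exp1_scenarios())
  path <- tempfile(fileext = ".yaml")
  specs <- build_exp2_scenarios()[1:3]
  write_scenarios(specs, path)
  back <- read_scenarios(path)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$initial_states, specs[[i]]$initial_states)
    expect_equal(back[[i]]$ped_priority, specs[[i]]$ped_priority)
    expect_equal(back[[i]]$dt, specs[[i]]$dt)
  }
})

test_that("spec invariants are validated", {
  expect_error(kinematic_state(10, -1))
  expect_error(script_profile("constant_decel_between_distances", v0 = 10,
                              decel_start_dist = 2, decel_end_dist = 5))
  expect_error(scenario_spec("pedestrian",
                             list(pedestrian = kinematic_state(1, 0),
                                  driver = kinematic_state(1, 0)),
                             scripts = list()),
               "modeled or scripted")
  expect_error(mph_to_ms(27), "fixed conversions")
  expect_equal(mph_to_ms(c(25, 30, 35)), c(11.2, 13.4, 15.6))
})
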