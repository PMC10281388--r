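# Shared fixtures for the test suite.  Everything is generated in code.

# a one-agent scenario with the "other" agent effectively absent
lone_scenario <- function(role = "pedestrian", dist = 10, speed = 0,
                          duration = 15, dt = 0.1) {
  other <- if (role == "pedestrian") "driver" else "pedestrian"
  states <- list(
    pedestrian = if (role == "pedestrian") kinematic_state(dist, speed)
                 else kinematic_state(1e6, 0),
    driver = if (role == "driver") kinematic_state(dist, speed)
             else kinematic_state(1e6, 13.4)
  )
  scripts <- setNames(list(script_profile("constant_speed",
                                          v0 = if (other == "driver") 13.4
                                               else 0)),
                      other)
  scenario_spec(modeled_roles = role, initial_states = states,
                scripts = scripts, duration = duration, dt = dt)
}

# a synthetic trace data.frame with the engine's column layout
synthetic_trace <- function(t, ped_d, ped_v, drv_d, drv_v, drv_a = NULL,
                            spec = NULL, v_free = c(pedestrian = 1.5,
                                                    driver = 13.4)) {
  if (is.null(drv_a)) drv_a <- c(diff(drv_v) / diff(t), 0)
  ped_a <- c(diff(ped_v) / diff(t), 0)
  zone_p <- if (is.null(spec)) 3.5 else zone_length(spec$geometry, "pedestrian")
  zone_v <- if (is.null(spec)) 4.5 else zone_length(spec$geometry, "driver")
  mk <- function(role, d, v, a, zone) {
    data.frame(t = t, d = d, v = v, a = a, control = NA_real_,
               action = NA_real_, P_first = NA_real_, P_second = NA_real_,
               Vhat_null = NA_real_, Vhat_best = NA_real_,
               percept_pos = NA_real_, percept_speed = NA_real_,
               kal_pos_var = NA_real_, kal_speed_var = NA_real_,
               AO_first = NA_real_, AO_second = NA_real_,
               in_conflict = as.numeric(d <= -0.05 & d > -zone),
               role = role, modeled = TRUE)
  }
  tr <- rbind(mk("pedestrian", ped_d, ped_v, ped_a, zone_p),
              mk("driver", drv_d, drv_v, drv_a, zone_v))
  if (is.null(spec)) {
    spec <- scenario_spec(modeled_roles = c("pedestrian", "driver"),
                          initial_states = list(
                            pedestrian = kinematic_state(max(ped_d[1], 0),
                                                         ped_v[1]),
                            driver = kinematic_state(max(drv_d[1], 0),
                                                     drv_v[1])),
                          duration = max(t), dt = t[2] - t[1])
  }
  attr(tr, "spec") <- spec
  attr(tr, "v_free") <- v_free
  class(tr) <- c("crossim_trace", class(tr))
  tr
}
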