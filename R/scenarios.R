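# Scenario definitions: interaction geometry, scripted trajectories, and
# factories for the phenomenon-test, encounter, and experiment scenario sets.

#' Speed conversions used throughout the scenario factories
#'
#' Nominal approach speeds in miles per hour mapped to the rounded m/s values
#' used in the experimental designs (25 -> 11.2, 30 -> 13.4, 35 -> 15.6).
#'
#' @param mph numeric vector of speeds in miles per hour (25, 30 or 35)
#' @return speeds in m/s
#' @export
mph_to_ms <- function(mph) {
  tab <- c(`25` = 11.2, `30` = 13.4, `35` = 15.6)
  key <- as.character(mph)
  if (any(!key %in% names(tab))) {
    stop("only the design speeds 25, 30, 35 mph have fixed conversions")
  }
  unname(tab[key])
}

#' Conflict-space geometry
#'
#' Each agent moves along its own 1-D path; the contested road space is the
#' stretch of each path between that agent's conflict-space entry and exit.
#' The pedestrian crosses the full lane width; the vehicle occupies the
#' pedestrian's walking corridor for its own length plus the corridor width.
#'
#' @param lane_width lane width crossed by the pedestrian, m
#' @param vehicle_length vehicle length, m
#' @param corridor_width width of the pedestrian walking corridor, m
#' @param eye_height observer eye height used by the distance-from-visual-angle
#'   sensory noise model, m
#' @return object of class `crossim_geometry`
#' @export
conflict_geometry <- function(lane_width = 3.5, vehicle_length = 4.0,
                              corridor_width = 0.5, eye_height = 1.6) {
  stopifnot(lane_width > 0, vehicle_length > 0, corridor_width > 0,
            eye_height > 0)
  g <- list(
    ped_entry_dist = 0,
    ped_exit_dist = lane_width,
    veh_entry_dist = 0,
    veh_exit_dist = corridor_width + vehicle_length,
    lane_width = lane_width,
    vehicle_length = vehicle_length,
    corridor_width = corridor_width,
    eye_height = eye_height
  )
  stopifnot(g$ped_exit_dist > g$ped_entry_dist,
            g$veh_exit_dist > g$veh_entry_dist)
  structure(g, class = "crossim_geometry")
}

#' Conflict-zone length along one agent's path
#'
#' @param geometry a [conflict_geometry()]
#' @param role `"pedestrian"` or `"driver"`
#' @return zone length in m
#' @export
zone_length <- function(geometry, role) {
  role <- match.arg(role, c("pedestrian", "driver"))
  if (role == "pedestrian") {
    geometry$ped_exit_dist - geometry$ped_entry_dist
  } else {
    geometry$veh_exit_dist - geometry$veh_entry_dist
  }
}

#' Kinematic state of one agent
#'
#' @param dist_to_conflict signed distance along the agent's own path to its
#'   conflict-space entry (positive before entry), m
#' @param speed speed, m/s (non-negative)
#' @param accel acceleration, m/s^2
#' @return object of class `crossim_state`
#' @export
kinematic_state <- function(dist_to_conflict, speed, accel = 0) {
  stopifnot(is.finite(dist_to_conflict), speed >= 0, is.finite(accel))
  structure(list(dist_to_conflict = dist_to_conflict, speed = speed,
                 accel = accel),
            class = "crossim_state")
}

#' Scripted (non-modeled) agent movement profile
#'
#' @param kind `"constant_speed"`, `"constant_decel_between_distances"` or
#'   `"predefined_series"`
#' @param v0 initial speed, m/s
#' @param decel_start_dist,decel_end_dist for the yielding profile: the
#'   deceleration is constant while the agent is between these two distances
#'   from its conflict-space entry; the implied deceleration is
#'   v0^2 / (2 (start - end))
#' @param series_t,series_v for `"predefined_series"`: time nodes (s, starting
#'   at 0) and speeds (m/s), linearly interpolated
#' @return object of class `crossim_script`
#' @export
script_profile <- function(kind = c("constant_speed",
                                    "constant_decel_between_distances",
                                    "predefined_series"),
                           v0, decel_start_dist = NULL, decel_end_dist = NULL,
                           series_t = NULL, series_v = NULL) {
  kind <- match.arg(kind)
  stopifnot(v0 >= 0)
  if (kind == "constant_decel_between_distances") {
    stopifnot(!is.null(decel_start_dist), !is.null(decel_end_dist),
              decel_start_dist > decel_end_dist, decel_end_dist >= 0)
    if (!is.finite(v0^2 / (2 * (decel_start_dist - decel_end_dist)))) {
      stop("implied deceleration is not finite")
    }
  }
  if (kind == "predefined_series") {
    stopifnot(length(series_t) == length(series_v), length(series_t) >= 2,
              series_t[1] == 0, !is.unsorted(series_t), all(series_v >= 0))
  }
  structure(list(kind = kind, v0 = v0, decel_start_dist = decel_start_dist,
                 decel_end_dist = decel_end_dist, series_t = series_t,
                 series_v = series_v),
            class = "crossim_script")
}

#' Full definition of one interaction episode
#'
#' @param modeled_roles character vector, subset of
#'   `c("pedestrian", "driver")`: the agents controlled by the cognitive model
#' @param initial_states named list of [kinematic_state()] for `pedestrian`
#'   and `driver`
#' @param scripts named list of [script_profile()] for each non-modeled role
#' @param ped_priority does the pedestrian have formal crossing priority
#'   (zebra crossing)?
#' @param geometry a [conflict_geometry()]
#' @param duration simulated duration, s
#' @param dt simulation time step, s
#' @param tta_offset offset applied to the vehicle's initial time-to-arrival
#'   relative to the scenario's base kinematics, s (bookkeeping field)
#' @param name scenario label
#' @param phenomenon targeted phenomenon label, if any
#' @param lead optional lead vehicle for the two-vehicle crossing experiment:
#'   `list(state = kinematic_state(...), script = script_profile(...))`
#' @param meta free-form metadata list (e.g. design-cell identifiers)
#' @return object of class `crossim_scenario`
#' @export
scenario_spec <- function(modeled_roles, initial_states, scripts = list(),
                          ped_priority = FALSE,
                          geometry = conflict_geometry(), duration = 15,
                          dt = 0.1, tta_offset = 0, name = NULL,
                          phenomenon = NULL, lead = NULL, meta = list()) {
  roles <- c("pedestrian", "driver")
  stopifnot(all(modeled_roles %in% roles), length(modeled_roles) >= 1,
            duration > 0, dt > 0)
  scripted_roles <- setdiff(roles, modeled_roles)
  if (!setequal(names(scripts), scripted_roles)) {
    stop("every agent must be either modeled or scripted")
  }
  stopifnot(setequal(names(initial_states), roles))
  for (r in roles) stopifnot(inherits(initial_states[[r]], "crossim_state"))
  structure(list(modeled_roles = modeled_roles,
                 initial_states = initial_states, scripts = scripts,
                 ped_priority = isTRUE(ped_priority), geometry = geometry,
                 duration = duration, dt = dt, tta_offset = tta_offset,
                 name = name, phenomenon = phenomenon, lead = lead,
                 meta = meta),
            class = "crossim_scenario")
}

#' Exact kinematics of a scripted agent
#'
#' @param spec a [scenario_spec()]
#' @param role a role scripted in `spec`
#' @param t time (s), vectorized
#' @return list with numeric vectors `dist_to_conflict`, `speed`, `accel`
#' @export
scripted_state <- function(spec, role, t) {
  if (role %in% spec$modeled_roles) {
    stop("role '", role, "' is modeled, not scripted")
  }
  prof <- spec$scripts[[role]]
  d0 <- spec$initial_states[[role]]$dist_to_conflict
  script_state_at(prof, d0, t)
}

# closed-form scripted kinematics from a profile and initial distance
script_state_at <- function(prof, d0, t) {
  v0 <- prof$v0
  if (prof$kind == "constant_speed") {
    return(list(dist_to_conflict = d0 - v0 * t,
                speed = rep(v0, length(t)),
                accel = rep(0, length(t))))
  }
  if (prof$kind == "constant_decel_between_distances") {
    a <- v0^2 / (2 * (prof$decel_start_dist - prof$decel_end_dist))
    if (d0 > prof$decel_start_dist) {
      t1 <- (d0 - prof$decel_start_dist) / v0
      dstart <- prof$decel_start_dist
    } else {
      t1 <- 0
      dstart <- d0
    }
    tstop <- v0 / a
    tau <- pmax(t - t1, 0)
    taus <- pmin(tau, tstop)
    d <- ifelse(t <= t1, d0 - v0 * t,
                dstart - (v0 * taus - 0.5 * a * taus^2))
    v <- ifelse(t <= t1, v0, pmax(v0 - a * tau, 0))
    ac <- ifelse(t > t1 & tau < tstop, -a, 0)
    return(list(dist_to_conflict = d, speed = v, accel = ac))
  }
  # predefined series: linear speed interpolation, exact position integral
  st <- prof$series_t
  sv <- prof$series_v
  # cumulative advance at the nodes (trapezoid is exact for linear speed)
  adv <- c(0, cumsum(diff(st) * (head(sv, -1) + tail(sv, -1)) / 2))
  v <- numeric(length(t))
  x <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti >= st[length(st)]) {
      v[i] <- sv[length(sv)]
      x[i] <- adv[length(adv)] + (ti - st[length(st)]) * v[i]
    } else {
      j <- findInterval(ti, st)
      f <- (ti - st[j]) / (st[j + 1] - st[j])
      v[i] <- sv[j] + f * (sv[j + 1] - sv[j])
      x[i] <- adv[j] + (ti - st[j]) * (sv[j] + v[i]) / 2
    }
  }
  a <- c(diff(sv) / diff(st), 0)
  ai <- a[pmin(findInterval(t, st), length(a))]
  list(dist_to_conflict = d0 - x, speed = v, accel = ai)
}

# ---------------------------------------------------------------------------
# scenario factories
# ---------------------------------------------------------------------------

#' Phenomenon-test scenarios
#'
#' One scenario per targeted phenomenon, each in three kinematic variants
#' obtained by offsetting the vehicle's initial time-to-arrival (TTA) by
#' \{-0.5, 0, +0.5\} s.  Driver-modeled scenarios (priority assertion and
#' short-stopping) face a scripted pedestrian standing near its conflict
#' entry with crossing priority; pedestrian-modeled scenarios (yield
#' acceptance hesitation, early yield acceptance, gap acceptance hesitation)
#' start the pedestrian walking at its equilibrium speed, 3 s from the
#' conflict space, facing a scripted yielding or constant-speed car.
#'
#' @param base_tta base vehicle time-to-arrival at the conflict space, s
#' @param gap_tta base vehicle TTA for the gap-acceptance scenario, s;
#'   larger than `base_tta` so that the gap is objectively acceptable at the
#'   pedestrian's equilibrium speed (hesitation then reflects risk aversion,
#'   not a physically unacceptable gap)
#' @param offsets TTA offsets defining the kinematic variants, s
#' @param v_free_ped,v_free_veh free (equilibrium) speeds, m/s
#' @param ped_wait_dist distance of the waiting pedestrian from its conflict
#'   entry in the driver-modeled scenarios, m
#' @param ped_cross_start,ped_cross_speed in the driver-modeled scenarios
#'   the scripted pedestrian stands at the curb and then crosses at
#'   `ped_cross_speed` from `ped_cross_start` on, giving the episode a
#'   closure against which yielding (and getting stuck) is measurable
#' @param geometry a [conflict_geometry()]
#' @param dt simulation step, s
#' @param duration simulated duration, s
#' @param decel_start_dist,decel_end_dist yielding-profile distances, m
#' @return list of [scenario_spec()]; 5 phenomena x `length(offsets)` variants
#' @export
build_phenomenon_scenarios <- function(base_tta = 3, gap_tta = 5.5,
                                       offsets = c(-0.5, 0, 0.5),
                                       v_free_ped = 1.5, v_free_veh = 13.4,
                                       ped_wait_dist = 1.5,
                                       ped_cross_start = 8,
                                       ped_cross_speed = 1.2,
                                       geometry = conflict_geometry(),
                                       dt = 0.1, duration = 18,
                                       decel_start_dist = 38.5,
                                       decel_end_dist = 2.5) {
  specs <- list()
  phen_driver <- c("priority_assertion", "short_stopping")
  phen_ped <- c("yield_acceptance_hesitation", "early_yield_acceptance",
                "gap_acceptance_hesitation")
  for (ph in c(phen_driver, phen_ped)) {
    for (off in offsets) {
      tta <- (if (ph == "gap_acceptance_hesitation") gap_tta else base_tta) +
        off
      veh_d0 <- v_free_veh * tta
      lab <- sprintf("%s/tta%+.1f", ph, off)
      if (ph %in% phen_driver) {
        spec <- scenario_spec(
          modeled_roles = "driver",
          initial_states = list(
            pedestrian = kinematic_state(ped_wait_dist, 0),
            driver = kinematic_state(veh_d0, v_free_veh)
          ),
          scripts = list(pedestrian = script_profile(
            "predefined_series", v0 = 0,
            series_t = c(0, ped_cross_start, ped_cross_start + 0.4),
            series_v = c(0, 0, ped_cross_speed))),
          ped_priority = TRUE, geometry = geometry, duration = duration,
          dt = dt, tta_offset = off, name = lab, phenomenon = ph
        )
      } else {
        yielding <- ph %in% c("yield_acceptance_hesitation",
                              "early_yield_acceptance")
        script <- if (yielding) {
          script_profile("constant_decel_between_distances", v0 = v_free_veh,
                         decel_start_dist = min(decel_start_dist, veh_d0),
                         decel_end_dist = decel_end_dist)
        } else {
          script_profile("constant_speed", v0 = v_free_veh)
        }
        spec <- scenario_spec(
          modeled_roles = "pedestrian",
          initial_states = list(
            pedestrian = kinematic_state(3 * v_free_ped, v_free_ped),
            driver = kinematic_state(veh_d0, v_free_veh)
          ),
          scripts = list(driver = script),
          ped_priority = FALSE, geometry = geometry, duration = duration,
          dt = dt, tta_offset = off, name = lab, phenomenon = ph
        )
      }
      specs[[lab]] <- spec
    }
  }
  specs
}

#' Interactive (two-agent) scenarios for the stochastic screen
#'
#' Three scenarios with both agents model-controlled: a two-agent version of
#' the gap-acceptance scenario (same initial conditions as the one-agent
#' version), and two encounter scenarios in which both agents travel at their
#' equilibrium speeds 3 s from the conflict space, with and without
#' pedestrian priority.
#'
#' @inheritParams build_phenomenon_scenarios
#' @return list of 3 [scenario_spec()]
#' @export
build_encounter_scenarios <- function(v_free_ped = 1.5, v_free_veh = 13.4,
                                      gap_tta = 5.5,
                                      geometry = conflict_geometry(),
                                      dt = 0.025, duration = 20) {
  mk <- function(name, priority, veh_tta) {
    scenario_spec(
      modeled_roles = c("pedestrian", "driver"),
      initial_states = list(
        pedestrian = kinematic_state(3 * v_free_ped, v_free_ped),
        driver = kinematic_state(veh_tta * v_free_veh, v_free_veh)
      ),
      scripts = list(), ped_priority = priority, geometry = geometry,
      duration = duration, dt = dt, name = name
    )
  }
  list(
    gap_acceptance_two_agent = mk("gap_acceptance_two_agent", FALSE, gap_tta),
    encounter_no_priority = mk("encounter_no_priority", FALSE, 3),
    encounter_priority = mk("encounter_priority", TRUE, 3)
  )
}

#' Crossing-experiment scenario set 1 (two approaching vehicles)
#'
#' The pedestrian starts stationary 1 m from the conflict space and faces two
#' vehicles at one of three speeds (25/30/35 mph), separated by a time gap of
#' 2-5 s.  The lead vehicle starts 3 s from completely passing the
#' pedestrian; the second vehicle either keeps constant speed or yields with
#' constant deceleration between 38.5 m and 2.5 m from the crossing.
#'
#' @param speeds_mph vehicle approach speeds, mph
#' @param gaps inter-vehicle time gaps, s
#' @param geometry a [conflict_geometry()]
#' @param dt simulation step, s
#' @param duration simulated duration, s
#' @return list of 24 [scenario_spec()] (3 speeds x 4 gaps x 2 behaviors)
#' @export
build_exp1_scenarios <- function(speeds_mph = c(25, 30, 35), gaps = 2:5,
                                 geometry = conflict_geometry(),
                                 dt = 0.025, duration = 20) {
  specs <- list()
  zone_veh <- zone_length(geometry, "driver")
  for (mph in speeds_mph) {
    v <- mph_to_ms(mph)
    for (gap in gaps) {
      for (yielding in c(FALSE, TRUE)) {
        lead_d0 <- 3 * v - zone_veh # rear clears the crossing at t = 3 s
        veh2_d0 <- lead_d0 + gap * v
        script <- if (yielding) {
          script_profile("constant_decel_between_distances", v0 = v,
                         decel_start_dist = min(38.5, veh2_d0),
                         decel_end_dist = 2.5)
        } else {
          script_profile("constant_speed", v0 = v)
        }
        lab <- sprintf("exp1/v%.1f/gap%d/%s", v, gap,
                       if (yielding) "yield" else "const")
        specs[[lab]] <- scenario_spec(
          modeled_roles = "pedestrian",
          initial_states = list(
            pedestrian = kinematic_state(1, 0),
            driver = kinematic_state(veh2_d0, v)
          ),
          scripts = list(driver = script),
          ped_priority = FALSE, geometry = geometry, duration = duration,
          dt = dt, name = lab,
          lead = list(state = kinematic_state(lead_d0, v),
                      script = script_profile("constant_speed", v0 = v)),
          meta = list(speed_mph = mph, speed = v, gap = gap,
                      yielding = yielding)
        )
      }
    }
  }
  specs
}

#' Crossing-experiment scenario set 2 (interactive, with/without zebra)
#'
#' Both agents are model-controlled.  The pedestrian starts stationary
#' 1.95 m from the conflict space; the driver approaches at 30 mph at an
#' initial time-to-arrival equal to the design time gap minus one second.
#' Each of the five gaps is crossed with pedestrian priority (zebra) present
#' or absent; the lane is 4.5 m wide.
#'
#' @param gaps design time gaps, s
#' @param geometry a [conflict_geometry()]; defaults to a 4.5 m lane
#' @param dt simulation step, s
#' @param duration simulated duration, s
#' @return list of 10 [scenario_spec()] (5 gaps x 2 priority conditions)
#' @export
build_exp2_scenarios <- function(gaps = 3:7,
                                 geometry = conflict_geometry(lane_width = 4.5),
                                 dt = 0.025, duration = 20) {
  v <- mph_to_ms(30)
  specs <- list()
  for (gap in gaps) {
    for (priority in c(FALSE, TRUE)) {
      lab <- sprintf("exp2/gap%d/%s", gap, if (priority) "zebra" else "plain")
      specs[[lab]] <- scenario_spec(
        modeled_roles = c("pedestrian", "driver"),
        initial_states = list(
          pedestrian = kinematic_state(1.95, 0),
          driver = kinematic_state(v * (gap - 1), v)
        ),
        scripts = list(), ped_priority = priority, geometry = geometry,
        duration = duration, dt = dt, name = lab,
        meta = list(gap = gap, priority = priority)
      )
    }
  }
  specs
}

# ---------------------------------------------------------------------------
# serialization
# ---------------------------------------------------------------------------

spec_to_plain <- function(spec) {
  pl <- unclass(spec)
  pl$geometry <- unclass(pl$geometry)
  pl$initial_states <- lapply(pl$initial_states, unclass)
  pl$scripts <- lapply(pl$scripts, function(s) Filter(Negate(is.null),
                                                      unclass(s)))
  if (!is.null(pl$lead)) {
    pl$lead <- list(state = unclass(pl$lead$state),
                    script = Filter(Negate(is.null), unclass(pl$lead$script)))
  }
  Filter(Negate(is.null), pl)
}

#' Write a scenario set to a YAML file
#'
#' @param specs list of [scenario_spec()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_scenarios <- function(specs, path) {
  yaml::write_yaml(lapply(specs, spec_to_plain), path)
  invisible(path)
}

#' Read a scenario set written by [write_scenarios()]
#'
#' @param path YAML file
#' @return list of [scenario_spec()]
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(pl) {
    geom <- do.call(conflict_geometry,
                    pl$geometry[c("lane_width", "vehicle_length",
                                  "corridor_width", "eye_height")])
    states <- lapply(pl$initial_states, function(s) {
      kinematic_state(s$dist_to_conflict, s$speed, s$accel)
    })
    scripts <- lapply(pl$scripts, function(s) do.call(script_profile, s))
    lead <- NULL
    if (!is.null(pl$lead)) {
      lead <- list(
        state = kinematic_state(pl$lead$state$dist_to_conflict,
                                pl$lead$state$speed, pl$lead$state$accel),
        script = do.call(script_profile, pl$lead$script)
      )
    }
    scenario_spec(pl$modeled_roles, states, scripts, pl$ped_priority, geom,
                  pl$duration, pl$dt, pl$tta_offset, pl$name, pl$phenomenon,
                  lead, if (is.null(pl$meta)) list() else pl$meta)
  })
}
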