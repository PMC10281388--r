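# Behavior metrics and phenomenon flags, and collision / non-progression
# detection.

trace_role <- function(trace, role) {
  trace[trace$role == role, , drop = FALSE]
}

# an agent has entered once clearly past its entry line (tolerance keeps an
# agent waiting exactly at the line from counting as inside)
entry_time <- function(tr) {
  i <- which(tr$d <= -0.05)
  if (length(i) == 0) NA_real_ else tr$t[i[1]]
}

#' Behavior metrics of one simulated episode
#'
#' Computes the metric set used by the phenomenon screens: mean-speed ratios
#' to the free speed (from episode start until the agent's own conflict
#' entry), the vehicle speed at the moment the pedestrian enters the
#' conflict space, the driver's mean excess deceleration over its yielding
#' phase (actual deceleration minus the deceleration required to stop at the
#' conflict entry), the distance from the conflict entry at which the
#' vehicle first stops, the pedestrian movement-onset and crossing times,
#' and the interaction outcome.
#'
#' @param trace a `crossim_trace`
#' @param spec the [scenario_spec()] that produced it (defaults to the
#'   trace attribute)
#' @param context `"screen"`, `"exp1"` or `"exp2"`; selects the
#'   non-progression rule
#' @param onset_speed pedestrian movement-onset threshold, m/s
#' @return list of class `crossim_metrics`
#' @export
compute_metrics <- function(trace, spec = attr(trace, "spec"),
                            context = c("screen", "exp1", "exp2"),
                            onset_speed = 0.1) {
  context <- match.arg(context)
  v_free <- attr(trace, "v_free")
  ped <- trace_role(trace, "pedestrian")
  drv <- trace_role(trace, "driver")
  t_entry_ped <- entry_time(ped)
  t_entry_drv <- entry_time(drv)

  mean_speed_until_entry <- function(tr, t_entry) {
    upto <- if (is.na(t_entry)) tr else tr[tr$t <= t_entry, , drop = FALSE]
    mean(upto$v)
  }
  ped_ratio <- mean_speed_until_entry(ped, t_entry_ped) /
    v_free[["pedestrian"]]
  veh_ratio <- mean_speed_until_entry(drv, t_entry_drv) / v_free[["driver"]]

  v_at_cross <- if (is.na(t_entry_ped)) {
    NA_real_
  } else {
    drv$v[which(drv$t >= t_entry_ped)[1]]
  }

  # driver yielding phase: decelerating while approaching the crossing
  yielding <- drv$a < -0.05 & drv$d > 0 & drv$v > 1e-6
  mean_excess <- NA_real_
  if (any(yielding)) {
    from <- which(yielding)[1]
    phase <- seq(from, nrow(drv))
    phase <- phase[drv$d[phase] > 0 & drv$v[phase] > 1e-6]
    req <- drv$v[phase]^2 / (2 * drv$d[phase])
    mean_excess <- mean(pmax(-drv$a[phase], 0) - req)
  }

  stopped <- which(drv$v <= 1e-6 & drv$d > 0)
  final_stop <- if (length(stopped) == 0) NA_real_ else drv$d[stopped[1]]

  # crossing onset: the onset of the movement episode that actually leads
  # into the conflict space (a pedestrian may first step up to the curb and
  # wait there; that approach movement is not a crossing initiation)
  t_onset <- NA_real_
  moving <- ped$v > onset_speed
  if (any(moving)) {
    ie <- which(ped$d <= -0.05)
    upto <- if (length(ie) == 0) nrow(ped) else ie[1]
    stopped <- which(ped$v[seq_len(upto)] <= onset_speed)
    from <- if (length(stopped) == 0) 1 else max(stopped)
    idx <- which(moving & seq_along(moving) >= from & seq_along(moving) <= upto)
    if (length(idx) > 0) t_onset <- ped$t[idx[1]]
  }
  cit <- NA_real_
  if (!is.null(spec$lead)) {
    lead_exit <- lead_exit_time(spec)
    cit <- if (is.na(t_onset)) NA_real_ else t_onset - lead_exit
  }

  outcome <- if (is.na(t_entry_ped) && is.na(t_entry_drv)) {
    "none"
  } else if (is.na(t_entry_drv) || (!is.na(t_entry_ped) &&
                                    t_entry_ped < t_entry_drv)) {
    "ped_first"
  } else {
    "veh_first"
  }

  cn <- detect_collision_nonprogression(trace, spec, context)

  structure(list(ped_speed_ratio = ped_ratio, veh_speed_ratio = veh_ratio,
                 veh_speed_at_ped_crossing = v_at_cross,
                 mean_excess_decel = mean_excess,
                 final_stop_distance = final_stop,
                 crossing_onset_time = t_onset,
                 crossing_initiation_time = cit,
                 ped_entry_time = t_entry_ped, veh_entry_time = t_entry_drv,
                 outcome = outcome, collision = cn$collision,
                 nonprogression = cn$nonprogression),
            class = "crossim_metrics")
}

# time at which the lead vehicle's rear clears the crossing location
lead_exit_time <- function(spec) {
  zone <- zone_length(spec$geometry, "driver")
  tt <- seq(0, spec$duration, by = spec$dt)
  st <- script_state_at(spec$lead$script, spec$lead$state$dist_to_conflict, tt)
  i <- which(st$dist_to_conflict <= -zone)
  if (length(i) == 0) return(NA_real_)
  tt[i[1]]
}

#' Collision and non-progression detection
#'
#' A collision is any step with both agents simultaneously inside their
#' conflict-space occupancy intervals.  Non-progression follows the context
#' rule: for the two-vehicle crossing experiment, the pedestrian failing to
#' cross even though the (yielding) car has fully stopped; for interactive
#' contexts, at least one agent failing to enter the conflict space within
#' 20 s.
#'
#' @inheritParams compute_metrics
#' @param horizon non-progression horizon for interactive contexts, s
#' @return list with logicals `collision` and `nonprogression`
#' @export
detect_collision_nonprogression <- function(trace,
                                            spec = attr(trace, "spec"),
                                            context = c("screen", "exp1",
                                                        "exp2"),
                                            horizon = 20) {
  context <- match.arg(context)
  ped <- trace_role(trace, "pedestrian")
  drv <- trace_role(trace, "driver")
  collision <- any(ped$in_conflict == 1 & drv$in_conflict == 1)
  t_entry_ped <- entry_time(ped)
  t_entry_drv <- entry_time(drv)

  if (context == "exp1") {
    yielded <- any(drv$v <= 1e-6)
    nonprog <- is.na(t_entry_ped) && (yielded || max(ped$t) >= horizon)
  } else if (context == "exp2" ||
             length(spec$modeled_roles) == 2) {
    nonprog <- (is.na(t_entry_ped) || t_entry_ped > horizon) ||
      (is.na(t_entry_drv) || t_entry_drv > horizon)
  } else {
    # one-agent screen: the modeled agent should eventually progress
    role <- spec$modeled_roles
    te <- if (role == "pedestrian") t_entry_ped else t_entry_drv
    nonprog <- is.na(te)
  }
  list(collision = collision, nonprogression = nonprog)
}

#' Retention criteria for the model-selection screens
#'
#' Thresholds on the behavior metrics defining when a phenomenon counts as
#' exhibited, chosen to be inclusive.
#'
#' @param hesitation_ratio pedestrian mean-speed ratio below which
#'   yield/gap acceptance hesitation is flagged
#' @param assertion_ratio vehicle mean-speed ratio above which priority
#'   assertion is flagged
#' @param early_yield_speed vehicle speed at pedestrian crossing onset above
#'   which early yield acceptance is flagged, m/s
#' @param excess_decel mean excess deceleration above which short-stopping
#'   is considered, m/s^2
#' @param stop_distance_margin final stopping distance that must also be
#'   exceeded for short-stopping, m
#' @param min_phenomena_deterministic number of phenomena required to retain
#'   a parameterization from the deterministic screen
#' @param require_collision_free reject parameterizations with any collision
#' @param require_progression reject parameterizations with non-progression
#' @return list of class `crossim_criteria`
#' @export
retention_criteria <- function(hesitation_ratio = 0.98,
                               assertion_ratio = 1.02,
                               early_yield_speed = 0.01,
                               excess_decel = 0.05,
                               stop_distance_margin = 1,
                               min_phenomena_deterministic = 3,
                               require_collision_free = TRUE,
                               require_progression = TRUE) {
  structure(list(hesitation_ratio = hesitation_ratio,
                 assertion_ratio = assertion_ratio,
                 early_yield_speed = early_yield_speed,
                 excess_decel = excess_decel,
                 stop_distance_margin = stop_distance_margin,
                 min_phenomena_deterministic = min_phenomena_deterministic,
                 require_collision_free = require_collision_free,
                 require_progression = require_progression),
            class = "crossim_criteria")
}

#' Phenomenon flags from metric reports over kinematic variants
#'
#' A phenomenon is flagged when its defining inequality holds in any of the
#' kinematic (TTA) variants of its scenario.
#'
#' @param reports list of `crossim_metrics`, one per kinematic variant of
#'   one phenomenon's scenario
#' @param phenomenon which phenomenon the reports belong to
#' @param criteria a [retention_criteria()]
#' @return logical flag
#' @export
phenomenon_flag <- function(reports,
                            phenomenon = c("priority_assertion",
                                           "short_stopping",
                                           "yield_acceptance_hesitation",
                                           "early_yield_acceptance",
                                           "gap_acceptance_hesitation"),
                            criteria = retention_criteria()) {
  phenomenon <- match.arg(phenomenon)
  one <- function(m) {
    switch(phenomenon,
           priority_assertion = isTRUE(m$veh_speed_ratio >
                                         criteria$assertion_ratio),
           short_stopping = isTRUE(m$mean_excess_decel >
                                     criteria$excess_decel) &&
             isTRUE(m$final_stop_distance > criteria$stop_distance_margin),
           yield_acceptance_hesitation = isTRUE(m$ped_speed_ratio <
                                                  criteria$hesitation_ratio),
           early_yield_acceptance = isTRUE(m$veh_speed_at_ped_crossing >
                                             criteria$early_yield_speed),
           gap_acceptance_hesitation = isTRUE(m$ped_speed_ratio <
                                                criteria$hesitation_ratio))
  }
  any(vapply(reports, one, logical(1)))
}

#' Phenomenon flags for a set of per-phenomenon reports
#'
#' @param reports_by_phenomenon named list: phenomenon -> list of
#'   `crossim_metrics` over its kinematic variants
#' @param criteria a [retention_criteria()]
#' @return named logical vector over phenomena
#' @export
phenomenon_flags <- function(reports_by_phenomenon,
                             criteria = retention_criteria()) {
  vapply(names(reports_by_phenomenon), function(ph) {
    phenomenon_flag(reports_by_phenomenon[[ph]], ph, criteria)
  }, logical(1))
}
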