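# Motor-primitive locomotion control: stereotyped control adjustments
# superposed over a baseline, and calibration of the kinematic reward
# coefficients that set the agents' free (equilibrium) speeds.

#' Motor primitive: a stereotyped control-adjustment profile
#'
#' The primitive ramps linearly from 0 to 1 over `ramp_duration` and then
#' holds at 1, so a triggered action permanently shifts the commanded control
#' (speed for the pedestrian, acceleration for the driver) by its amplitude.
#'
#' @param ramp_duration ramp time, s
#' @return object of class `crossim_primitive`
#' @export
motor_primitive <- function(ramp_duration = 0.4) {
  stopifnot(ramp_duration > 0)
  structure(list(ramp_duration = ramp_duration), class = "crossim_primitive")
}

#' Primitive profile value G(i) at elapsed step i
#'
#' @param primitive a [motor_primitive()]
#' @param i elapsed steps since the action was triggered (vectorized)
#' @param dt simulation step, s
#' @return profile values in \[0, 1\]
#' @export
primitive_profile <- function(primitive, i, dt) {
  stopifnot(all(i >= 0), dt > 0)
  pmin(1, i * dt / primitive$ramp_duration)
}

#' Control history of one agent
#'
#' @param chosen_amps amplitude of the action chosen at each past step (0 for
#'   the null action)
#' @param baseline_control control level before any adjustment (commanded
#'   speed in m/s for a pedestrian, commanded acceleration in m/s^2 for a
#'   driver)
#' @param dt simulation step, s
#' @return object of class `crossim_history`
#' @export
control_history <- function(chosen_amps = numeric(), baseline_control = 0,
                            dt = 0.1) {
  stopifnot(dt > 0)
  structure(list(chosen_amps = chosen_amps,
                 baseline_control = baseline_control, dt = dt),
            class = "crossim_history")
}

#' Superposed control signal at step k
#'
#' The commanded control is the baseline plus the superposition of all
#' triggered primitives, each evaluated at its elapsed time.  For a
#' pedestrian the result is a commanded speed and is clamped at zero.
#'
#' @param history a [control_history()] covering steps 1..k (entry j holds
#'   the amplitude chosen at step j)
#' @param primitive a [motor_primitive()]
#' @param k step at which to evaluate the control (>= 1)
#' @param role `"pedestrian"` (speed control, clamped at 0) or `"driver"`
#'   (acceleration control)
#' @return commanded control value
#' @export
control_signal <- function(history, primitive, k,
                           role = c("driver", "pedestrian")) {
  role <- match.arg(role)
  stopifnot(k >= 1, length(history$chosen_amps) >= k)
  i <- 0:(k - 1)
  g <- history$chosen_amps[k - i]
  ctrl <- history$baseline_control +
    sum(g * primitive_profile(primitive, i, history$dt))
  if (role == "pedestrian") ctrl <- max(ctrl, 0)
  ctrl
}

#' Discrete action set for one role
#'
#' A symmetric set of control-adjustment amplitudes including the null
#' action of not adjusting control.
#'
#' @param role `"pedestrian"` (speed deltas, m/s) or `"driver"` (acceleration
#'   deltas, m/s^2)
#' @param amplitudes optional custom amplitudes (must include 0)
#' @return data.frame with columns `amplitude` and `is_null`
#' @export
default_action_set <- function(role = c("pedestrian", "driver"),
                               amplitudes = NULL) {
  role <- match.arg(role)
  if (is.null(amplitudes)) {
    amplitudes <- if (role == "pedestrian") {
      c(-1, -0.5, 0, 0.5, 1)
    } else {
      c(-2, -1, 0, 1, 2)
    }
  }
  if (!any(amplitudes == 0)) stop("the action set must include the null action")
  data.frame(amplitude = amplitudes, is_null = amplitudes == 0)
}

#' Calibrate kinematic reward coefficients to a target free speed
#'
#' The momentary kinematics reward is K(v, a) = k_g v - k_dv v^2 - k_da a^2.
#' Setting k_g = 2 k_dv v_free makes K maximal at v = v_free, a = 0, so a
#' lone agent settles at the free speed.
#'
#' @param v_free target free speed, m/s
#' @param k_dv speed-cost coefficient (default normalizes the maximum reward
#'   rate to 1)
#' @param k_da acceleration-cost coefficient
#' @return object of class `crossim_reward` with fields `k_g`, `k_dv`,
#'   `k_da`, `v_free`
#' @export
calibrate_kinematic_rewards <- function(v_free, k_dv = 1 / v_free^2,
                                        k_da = 0.05) {
  if (!is.finite(v_free) || v_free <= 0) stop("v_free must be positive")
  stopifnot(k_dv > 0, k_da > 0)
  structure(list(k_g = 2 * k_dv * v_free, k_dv = k_dv, k_da = k_da,
                 v_free = v_free),
            class = "crossim_reward")
}

#' Default reward parameters per role
#'
#' Pedestrian free speed 1.5 m/s (a brisk walk, reachable from standstill by
#' the default 0.5 m/s speed-adjustment lattice); driver free speed 13.4 m/s
#' (the 30 mph urban speed limit).  Acceleration-cost coefficients are set so
#' that a comfortable adjustment costs a small fraction of the maximum
#' progress reward.
#'
#' @param role `"pedestrian"` or `"driver"`
#' @param v_free optional free-speed override, m/s
#' @return a `crossim_reward`
#' @export
default_reward_params <- function(role = c("pedestrian", "driver"),
                                  v_free = NULL) {
  role <- match.arg(role)
  if (is.null(v_free)) v_free <- if (role == "pedestrian") 1.5 else 13.4
  k_da <- if (role == "pedestrian") 0.08 else 0.02
  calibrate_kinematic_rewards(v_free, k_dv = 1 / v_free^2, k_da = k_da)
}
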