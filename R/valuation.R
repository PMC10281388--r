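# Action valuation: short-term payoff (predict a fixed horizon ahead, reward
# kinematics minus collision and priority costs) and affordance-based
# long-term value (discounted reward integral along an access-order plan).

#' Valuation configuration
#'
#' @param scheme `"affordance"` (discounted long-term value of an access
#'   order, the default) or `"short_term"` (one-shot payoff at the
#'   prediction horizon)
#' @param role ego role; sets the plan acceleration bounds and the default
#'   conflict-zone lengths
#' @param T_P prediction horizon, s
#' @param discount_T exponential discount time constant, s
#' @param collision_cost cost applied on a predicted collision course
#'   (short-term scheme), and the cost rate applied during predicted
#'   simultaneous occupancy under an infeasible boundary plan (affordance
#'   scheme)
#' @param priority_cost cost of passing first against the other agent's
#'   priority
#' @param looming_weight weight of the rectified optical-expansion cost
#'   (0 disables looming)
#' @param squash_scale scale of the sigmoid mapping values to \[-1, 1\];
#'   `NULL` resolves to 1 for the short-term scheme and 1 / `discount_T`
#'   for the affordance scheme (so the ideal free-speed future maps to about
#'   0.75)
#' @param sigmoid `"tanh"` or `"arctan"`
#' @param dt_int integration step for the affordance reward integral, s
#' @param a_comf,a_max,a_dec_max plan acceleration bounds, m/s^2 (defaults by
#'   role)
#' @param zone_ego,zone_oth conflict-zone lengths along the ego and other
#'   paths, m (defaults from [conflict_geometry()])
#' @param entry_margin safety clearance demanded from vehicle positions, m:
#'   a vehicle is read as entering the conflict once within this distance
#'   of its entry (so a car stopping exactly at the line still blocks a
#'   pedestrian), and a driver plans its yielding stop this far short of
#'   the line; pedestrian positions carry no such margin
#' @param oth_has_priority does the other agent hold formal priority, so that
#'   the ego passing first violates it?
#' @param block_first forbid the pass-first access order (the lead-vehicle
#'   instruction constraint)
#' @param geometry optional [conflict_geometry()] used for zone defaults
#' @return object of class `crossim_valcfg`
#' @export
valuation_config <- function(scheme = c("affordance", "short_term"),
                             role = c("pedestrian", "driver"),
                             T_P = 0.5, discount_T = 10, collision_cost = 5,
                             priority_cost = 2, looming_weight = 0,
                             squash_scale = NULL,
                             sigmoid = c("tanh", "arctan"), dt_int = 0.1,
                             a_comf = NULL, a_max = NULL, a_dec_max = NULL,
                             zone_ego = NULL, zone_oth = NULL,
                             entry_margin = 1.5,
                             oth_has_priority = FALSE, block_first = FALSE,
                             geometry = conflict_geometry()) {
  scheme <- match.arg(scheme)
  role <- match.arg(role)
  sigmoid <- match.arg(sigmoid)
  stopifnot(T_P > 0, discount_T > 0, collision_cost >= 0, priority_cost >= 0,
            looming_weight >= 0, dt_int > 0)
  b <- plan_bounds(role)
  if (is.null(a_comf)) a_comf <- b[["a_comf"]]
  if (is.null(a_max)) a_max <- b[["a_max"]]
  if (is.null(a_dec_max)) a_dec_max <- b[["a_dec_max"]]
  if (is.null(zone_ego)) {
    zone_ego <- zone_length(geometry, role)
  }
  if (is.null(zone_oth)) {
    zone_oth <- zone_length(geometry,
                            if (role == "pedestrian") "driver" else "pedestrian")
  }
  if (is.null(squash_scale)) {
    squash_scale <- if (scheme == "short_term") 1 else 1 / discount_T
  }
  structure(list(scheme = match(scheme, c("short_term", "affordance")) - 1L,
                 scheme_name = scheme, role = role,
                 sigmoid = match(sigmoid, c("tanh", "arctan")) - 1L,
                 T_P = T_P, discount_T = discount_T,
                 collision_cost = collision_cost,
                 priority_cost = priority_cost,
                 looming_weight = looming_weight,
                 squash_scale = squash_scale, dt_int = dt_int,
                 a_comf = a_comf, a_max = a_max, a_dec_max = a_dec_max,
                 zone_ego = zone_ego, zone_oth = zone_oth,
                 entry_margin = entry_margin,
                 oth_has_priority = isTRUE(oth_has_priority),
                 block_first = isTRUE(block_first)),
            class = "crossim_valcfg")
}

#' Plan acceleration bounds per role
#'
#' @param role `"pedestrian"` or `"driver"`
#' @return named vector with `a_comf`, `a_max`, `a_dec_max` in m/s^2
#' @export
plan_bounds <- function(role = c("pedestrian", "driver")) {
  role <- match.arg(role)
  # a_dec_max is the *comfortable* planning deceleration, not the physical
  # limit: it sets the point of no return past which an agent no longer
  # considers ceding the space, which is what makes uncertain percepts
  # genuinely risky for the keep-going action
  if (role == "pedestrian") {
    c(a_comf = 0.8, a_max = 1.5, a_dec_max = 0.5)
  } else {
    c(a_comf = 2.0, a_max = 3.0, a_dec_max = 3.5)
  }
}

#' Ego agent state for valuation calls
#'
#' @param role `"pedestrian"` or `"driver"`
#' @param dist signed distance to the ego conflict-space entry, m
#' @param speed current speed, m/s
#' @param ctrl_now current commanded control (defaults to `speed` for a
#'   pedestrian and 0 for a driver)
#' @param ramp_rem remaining ramp times of pending motor primitives, s
#' @param ramp_amp amplitudes of the pending primitives
#' @param ramp_dur primitive ramp duration, s
#' @return plain list consumed by the valuation functions
#' @export
ego_state <- function(role = c("pedestrian", "driver"), dist, speed,
                      ctrl_now = NULL, ramp_rem = numeric(),
                      ramp_amp = numeric(), ramp_dur = 0.4) {
  role <- match.arg(role)
  if (is.null(ctrl_now)) ctrl_now <- if (role == "pedestrian") speed else 0
  stopifnot(length(ramp_rem) == length(ramp_amp), speed >= 0)
  list(role = match(role, c("pedestrian", "driver")) - 1L, d = dist,
       v = speed, ctrl_now = ctrl_now, ramp_rem = as.numeric(ramp_rem),
       ramp_amp = as.numeric(ramp_amp), ramp_dur = ramp_dur)
}

#' Projection parameters for the other agent's behaviors
#'
#' Under the pass-first behavior the other agent is projected to accelerate
#' at `assert_accel` toward its role-typical free speed when below it (and
#' to maintain speed otherwise); under pass-second it decelerates constantly
#' to stop at its conflict-space entry, capped at `a_stop_max`.
#'
#' @param role role of the projected (other) agent
#' @param assert_accel acceleration toward free speed under pass-first,
#'   m/s^2
#' @param v_free assumed role-typical free speed, m/s
#' @param a_stop_max cap on the stopping deceleration, m/s^2
#' @return plain list
#' @export
behavior_projection <- function(role = c("driver", "pedestrian"),
                                assert_accel = NULL, v_free = NULL,
                                a_stop_max = NULL) {
  role <- match.arg(role)
  if (role == "driver") {
    if (is.null(assert_accel)) assert_accel <- 1.5
    if (is.null(v_free)) v_free <- 13.4
    if (is.null(a_stop_max)) a_stop_max <- 4
  } else {
    if (is.null(assert_accel)) assert_accel <- 0.6
    if (is.null(v_free)) v_free <- 1.5
    if (is.null(a_stop_max)) a_stop_max <- 2
  }
  list(assert_accel = assert_accel, v_free = v_free, a_stop_max = a_stop_max)
}

# convert a crossim_valcfg to the flat list the C++ layer expects
valcfg_cpp <- function(config) {
  list(scheme = config$scheme, sigmoid = config$sigmoid, T_P = config$T_P,
       discount_T = config$discount_T,
       collision_cost = config$collision_cost,
       priority_cost = config$priority_cost,
       looming_weight = config$looming_weight,
       squash_scale = config$squash_scale, dt_int = config$dt_int,
       a_comf = config$a_comf, a_max = config$a_max,
       a_dec_max = config$a_dec_max, zone_ego = config$zone_ego,
       zone_oth = config$zone_oth,
       margin_ego = if (config$role == "driver") config$entry_margin else 0,
       margin_oth = if (config$role == "driver") 0 else config$entry_margin,
       oth_has_priority = config$oth_has_priority,
       block_first = config$block_first)
}

reward_cpp <- function(params) {
  list(k_g = params$k_g, k_dv = params$k_dv, k_da = params$k_da,
       v_free = params$v_free)
}

behavior_index <- function(behavior) {
  match.arg(behavior, c("pass_first", "pass_second"))
  match(behavior, c("pass_first", "pass_second")) - 1L
}

#' Predict the joint state a fixed time ahead
#'
#' The ego agent is propagated under its current control, its pending
#' motor-primitive ramps (efference copy) and one candidate action; the
#' other agent is propagated at constant acceleration from its perceived
#' position and speed, with speed clamped at zero.
#'
#' @param ego an [ego_state()]
#' @param action_amp candidate action amplitude
#' @param other_d,other_v perceived other-agent position (m) and speed (m/s)
#' @param other_accel assumed other-agent acceleration, m/s^2
#' @param horizon prediction horizon, s
#' @return list with `ego_d`, `ego_v`, `ego_a`, `other_d`, `other_v`
#' @export
predict_state <- function(ego, action_amp = 0, other_d = Inf, other_v = 0,
                          other_accel = 0, horizon = 0.5) {
  stopifnot(horizon > 0)
  cpp_predict_state(ego, action_amp, other_d, other_v, other_accel, horizon)
}

#' Momentary kinematics reward K(v, a)
#'
#' @param v speed, m/s
#' @param a acceleration, m/s^2
#' @param params a `crossim_reward` from [calibrate_kinematic_rewards()]
#' @return reward rate (vectorized)
#' @export
kinematic_reward <- function(v, a, params) {
  params$k_g * v - params$k_dv * v^2 - params$k_da * a^2
}

#' Short-term payoff value of a candidate action
#'
#' Predicts `T_P` ahead and returns K - C - R: the kinematics reward minus
#' the collision-course cost (constant-velocity occupancy overlap from the
#' predicted state) minus, for a driver facing pedestrian priority, the
#' deceleration-deficit priority cost.
#'
#' @inheritParams predict_state
#' @param behavior assumed other-agent behavior, `"pass_first"` or
#'   `"pass_second"`
#' @param config a [valuation_config()]
#' @param reward a `crossim_reward`
#' @param proj a [behavior_projection()] for the other agent
#' @return unconstrained value u
#' @export
short_term_value <- function(ego, action_amp, other_d, other_v,
                             behavior = "pass_first", config, reward,
                             proj = NULL) {
  if (is.null(proj)) {
    proj <- behavior_projection(if (config$role == "pedestrian") "driver"
                                else "pedestrian")
  }
  cpp_short_term_value(ego, action_amp, other_d, other_v,
                       behavior_index(behavior), reward_cpp(reward),
                       valcfg_cpp(config), proj)
}

#' Plan achieving one access order
#'
#' Constructs a kinematically bounded ego plan that passes the conflict
#' space before the other agent enters it (`"pass_first"`) or enters no
#' earlier than the other agent's exit (`"pass_second"`), with minimal
#' deviation from the current speed; kinematically impossible orders return
#' the least-violating boundary plan with `feasible = FALSE`.
#'
#' @inheritParams short_term_value
#' @param order access order to achieve
#' @return list with `feasible`, `t_entry`, `t_exit`, `other_t_entry`,
#'   `other_t_exit` and the piecewise-constant-acceleration `segments`
#' @export
plan_access_order <- function(ego, action_amp, other_d, other_v,
                              behavior = "pass_first",
                              order = c("pass_first", "pass_second"),
                              config, reward, proj = NULL) {
  order <- match.arg(order)
  if (is.null(proj)) {
    proj <- behavior_projection(if (config$role == "pedestrian") "driver"
                                else "pedestrian")
  }
  cpp_plan_access_order(ego, action_amp, other_d, other_v,
                        behavior_index(behavior),
                        match(order, c("pass_first", "pass_second")) - 1L,
                        reward_cpp(reward), valcfg_cpp(config), proj)
}

#' Affordance-based long-term value of a candidate action
#'
#' Applies the action over the prediction horizon, then follows the plan for
#' each access order, integrating the discounted kinematics reward (minus
#' looming, when enabled) numerically plus a closed-form steady-state tail,
#' and subtracting the priority cost for passing first against priority.
#' The action value is the maximum over the two access orders.
#'
#' @inheritParams short_term_value
#' @return list with `u` (the max over orders), `u_pass_first`,
#'   `u_pass_second`
#' @export
affordance_value <- function(ego, action_amp, other_d, other_v,
                             behavior = "pass_first", config, reward,
                             proj = NULL) {
  if (is.null(proj)) {
    proj <- behavior_projection(if (config$role == "pedestrian") "driver"
                                else "pedestrian")
  }
  cpp_affordance_value(ego, action_amp, other_d, other_v,
                       behavior_index(behavior), reward_cpp(reward),
                       valcfg_cpp(config), proj)
}

#' Value for the other agent of one of its behaviors
#'
#' The same valuation machinery with roles swapped: the other agent becomes
#' the value-holder, its behavior fixes its access order (and its projected
#' movement), and the ego agent is projected under a conditioning action
#' (the action-sensitive case) or under no adjustment.
#'
#' @param ego the ego [ego_state()] (the agent whose actions condition the
#'   estimate)
#' @param cond_amp conditioning ego action amplitude (0 for the
#'   action-insensitive case)
#' @param other_d,other_v perceived other-agent position and speed
#' @param behavior the other agent's behavior being valued
#' @param config_oth a [valuation_config()] expressed from the other agent's
#'   perspective (its role, its zone as `zone_ego`, `oth_has_priority` true
#'   when the ego agent holds priority)
#' @param reward_oth the other agent's assumed `crossim_reward`
#' @param proj_oth [behavior_projection()] for the other agent
#' @return unconstrained value for the other agent
#' @export
behavior_value <- function(ego, cond_amp, other_d, other_v,
                           behavior = "pass_first", config_oth, reward_oth,
                           proj_oth = NULL) {
  if (is.null(proj_oth)) {
    proj_oth <- behavior_projection(config_oth$role)
  }
  cpp_value_other(ego, cond_amp, other_d, other_v, behavior_index(behavior),
                  reward_cpp(reward_oth), valcfg_cpp(config_oth), proj_oth)
}

#' Sigmoid squashing of unconstrained values to \[-1, 1\]
#'
#' @param u unconstrained value (vectorized; `-Inf` maps to -1)
#' @param scale squash scale (1/reward)
#' @param sigmoid `"tanh"` or `"arctan"`
#' @return squashed value in \[-1, 1\]
#' @export
squash <- function(u, scale = 1, sigmoid = c("tanh", "arctan")) {
  sigmoid <- match.arg(sigmoid)
  out <- if (sigmoid == "tanh") {
    tanh(scale * u)
  } else {
    (2 / pi) * atan(scale * u * pi / 2)
  }
  out[u == -Inf] <- -1
  out[u == Inf] <- 1
  out
}
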