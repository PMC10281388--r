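# Theory-of-mind behavior estimation: per-behavior evidence from the other
# agent's estimated values and from observation of its motion, combined by
# softmax into behavior probabilities conditioned on the ego action.

#' Acceleration corresponding to a behavior of the other agent
#'
#' Pass-second maps to the constant deceleration that brings the other agent
#' to a stop at its conflict-space entry (capped at its maximum stopping
#' deceleration); pass-first maps to the configured assertive acceleration
#' toward the role-typical free speed (0 when already at or above it).  A
#' stopped agent maps to a non-negative acceleration under both behaviors.
#'
#' @param other_d,other_v perceived position (m) and speed (m/s) of the other
#'   agent
#' @param behavior `"pass_first"` or `"pass_second"`
#' @param proj a [behavior_projection()]
#' @return signed acceleration, m/s^2
#' @export
behavior_acceleration <- function(other_d, other_v,
                                  behavior = c("pass_first", "pass_second"),
                                  proj = behavior_projection("driver")) {
  behavior <- match.arg(behavior)
  cpp_behavior_accel(other_d, max(other_v, 0),
                     match(behavior, c("pass_first", "pass_second")) - 1L,
                     proj)
}

#' Belief about the other agent's intended access order
#'
#' Holds the observation-based evidence A_O per behavior and the accumulated
#' value-based evidence per (behavior, conditioning ego action), plus the
#' weights and time constants of the evidence machinery.
#'
#' @param n_cond number of conditioning ego actions (1 when
#'   action-insensitive)
#' @param beta_V weight of the value-based evidence (the observation weight
#'   is fixed to 1)
#' @param sigma_O sd of the Gaussian observation likelihood, m
#' @param T_Of forgetting time constant of the observation evidence, s
#' @param T_O1 time per observation evidence update, s
#' @return object of class `crossim_belief_b`
#' @export
behavior_belief <- function(n_cond = 1, beta_V = 2, sigma_O = 0.5,
                            T_Of = 2, T_O1 = 0.2) {
  stopifnot(n_cond >= 1, beta_V >= 0, sigma_O > 0, T_Of > 0, T_O1 > 0)
  structure(list(A_O = c(pass_first = 0, pass_second = 0),
                 V_ba = matrix(0, 2, n_cond,
                               dimnames = list(c("pass_first", "pass_second"),
                                               NULL)),
                 initialized = FALSE, beta_V = beta_V, sigma_O = sigma_O,
                 T_Of = T_Of, T_O1 = T_O1),
            class = "crossim_belief_b")
}

#' Update the accumulated value-based evidence
#'
#' The current squashed behavior values pass through the same low-pass /
#' noise recursion as the ego action values; on the first call the
#' accumulators are initialized to the current values (the value estimate
#' acts as the prior).
#'
#' @param belief a [behavior_belief()]
#' @param v_tilde 2 x n_cond matrix of current squashed behavior values
#' @param dt time step, s
#' @param T accumulator time constant, s (`dt` reproduces the no-accumulation
#'   limit)
#' @param sigma_V value-noise scale (0 for deterministic updates; noise uses
#'   the R random number generator)
#' @return updated belief
#' @export
update_value_evidence <- function(belief, v_tilde, dt, T = dt, sigma_V = 0) {
  stopifnot(all(dim(v_tilde) == dim(belief$V_ba)), dt > 0, T >= dt)
  if (!belief$initialized) {
    belief$V_ba[] <- v_tilde
    belief$initialized <- TRUE
    return(belief)
  }
  noise <- if (sigma_V > 0) {
    matrix(stats::rnorm(length(v_tilde), 0, sigma_V * sqrt(dt)),
           nrow(v_tilde))
  } else 0
  belief$V_ba <- (1 - dt / T) * belief$V_ba + (dt / T) * v_tilde + noise
  belief
}

#' Update the observation-based evidence
#'
#' Each behavior predicts the currently observed position from the previous
#' percept and the behavior's acceleration; the Gaussian log-likelihood of
#' the actual observation feeds a leaky accumulator with forgetting time
#' `T_Of` and update time `T_O1`.
#'
#' @param belief a [behavior_belief()]
#' @param pos_now currently perceived other-agent position, m
#' @param pos_prev,speed_prev previous percept of the other agent
#' @param dt time step, s
#' @param proj a [behavior_projection()] for the other agent
#' @return updated belief
#' @export
update_observation_evidence <- function(belief, pos_now, pos_prev, speed_prev,
                                        dt, proj = behavior_projection("driver")) {
  stopifnot(dt > 0)
  for (b in c("pass_first", "pass_second")) {
    a_b <- behavior_acceleration(pos_prev, speed_prev, b, proj)
    pred <- pos_prev - max(speed_prev, 0) * dt - 0.5 * a_b * dt^2
    ll <- stats::dnorm(pos_now, pred, belief$sigma_O, log = TRUE)
    belief$A_O[[b]] <- (1 - dt / belief$T_Of) * belief$A_O[[b]] +
      (dt / belief$T_O1) * ll
  }
  belief
}

#' Behavior probabilities given a conditioning ego action
#'
#' Softmax over behaviors of the combined evidence
#' beta_V * V_hat(b | a) + A_O(b), normally computed from the previous
#' step's stored evidence.
#'
#' @param belief a [behavior_belief()]
#' @param cond conditioning-action column index (1 when action-insensitive)
#' @return named probability vector over `pass_first`, `pass_second`
#' @export
behavior_probabilities <- function(belief, cond = 1) {
  A <- belief$beta_V * belief$V_ba[, cond] + belief$A_O
  e <- exp(A - max(A))
  p <- e / sum(e)
  names(p) <- c("pass_first", "pass_second")
  p
}
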