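# Action decisions: probability-weighted expected action value, noisy
# evidence accumulation, and threshold-gated selection against the null
# (no-adjustment) action.

#' Evidence accumulator over the action set
#'
#' @param n_actions number of actions
#' @param T accumulator time constant, s
#' @param sigma_V value-noise scale (squashed-value units per sqrt(s))
#' @param delta_V_th selection threshold over the null action's accumulated
#'   value
#' @param null_index index of the null action
#' @param V_hat optional initial accumulated values
#' @return object of class `crossim_accumulator`
#' @export
accumulator <- function(n_actions, T = 0.4, sigma_V = 0, delta_V_th = 0.05,
                        null_index = (n_actions + 1) %/% 2,
                        V_hat = rep(0, n_actions)) {
  stopifnot(T > 0, sigma_V >= 0, delta_V_th >= 0, length(V_hat) == n_actions,
            null_index >= 1, null_index <= n_actions, all(is.finite(V_hat)))
  structure(list(V_hat = V_hat, T = T, sigma_V = sigma_V,
                 delta_V_th = delta_V_th, null_index = null_index),
            class = "crossim_accumulator")
}

#' Expected action value over the other agent's behaviors
#'
#' @param values value of the action under each behavior
#' @param probs probability of each behavior (given this action); must sum
#'   to 1
#' @return the probability-weighted sum
#' @export
expected_action_value <- function(values, probs) {
  stopifnot(length(values) == length(probs),
            abs(sum(probs) - 1) < 1e-8)
  sum(probs * values)
}

#' One accumulation step
#'
#' First-order low-pass filtering of the noisy action values with additive
#' Gaussian value noise scaled by sqrt(dt).
#'
#' @param acc a [accumulator()]
#' @param inputs current noisy action values (one per action)
#' @param dt time step, s; must not exceed the time constant
#' @return updated accumulator; noise uses the R random number generator
#' @export
accumulate <- function(acc, inputs, dt) {
  stopifnot(length(inputs) == length(acc$V_hat), dt > 0)
  if (dt > acc$T) stop("dt > T gives an unstable accumulator update")
  noise <- if (acc$sigma_V > 0) {
    stats::rnorm(length(inputs), 0, acc$sigma_V * sqrt(dt))
  } else 0
  acc$V_hat <- (1 - dt / acc$T) * acc$V_hat + (dt / acc$T) * inputs + noise
  acc
}

#' Threshold-gated action selection
#'
#' Returns the index of the action with the highest accumulated value,
#' provided it exceeds the null action's accumulated value by more than the
#' threshold; otherwise the null action.  Ties break toward the null action,
#' then toward the smaller amplitude magnitude, then toward the lower index.
#'
#' @param acc a [accumulator()]
#' @param amplitudes action amplitudes (for the tie-break)
#' @return index of the selected action
#' @export
select_action <- function(acc, amplitudes) {
  stopifnot(length(amplitudes) == length(acc$V_hat))
  V <- acc$V_hat
  ni <- acc$null_index
  best <- ni
  for (i in seq_along(V)) {
    if (i == ni) next
    diff <- V[i] - V[best]
    if (diff > 1e-15) {
      best <- i
    } else if (abs(diff) <= 1e-15 && best != ni &&
               abs(amplitudes[i]) < abs(amplitudes[best])) {
      best <- i
    }
  }
  if (best != ni && V[best] - V[ni] > acc$delta_V_th) best else ni
}
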