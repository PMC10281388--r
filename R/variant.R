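# Model variants (which cognitive assumptions are switched on) and the free
# parameters each variant exposes to the model-selection grids.

#' Model variant definition
#'
#' Individual model assumptions can be disabled to create lower-complexity
#' variants.  Dependency constraints: action sensitivity requires value-based
#' behavior estimation, and Kalman filtering requires sensory noise.
#'
#' @param value_scheme `"short_term"` or `"affordance"`
#' @param obs_estimation observation-based behavior estimation
#' @param value_estimation value-based behavior estimation
#' @param action_sensitive condition the other's estimated values on the ego
#'   action
#' @param value_noise additive noise on the accumulated values
#' @param sensory_noise `"none"`, `"constant"` or `"distance_scaled"`
#' @param kalman Bayesian (Kalman) perceptual filtering with posterior
#'   sampling
#' @param accumulation evidence accumulation (low-pass filtering) of values
#' @param looming include the optical-expansion (looming) cost
#' @return object of class `crossim_variant`
#' @export
model_variant <- function(value_scheme = c("affordance", "short_term"),
                          obs_estimation = FALSE, value_estimation = FALSE,
                          action_sensitive = FALSE, value_noise = FALSE,
                          sensory_noise = c("none", "constant",
                                            "distance_scaled"),
                          kalman = FALSE, accumulation = FALSE,
                          looming = FALSE) {
  value_scheme <- match.arg(value_scheme)
  sensory_noise <- match.arg(sensory_noise)
  if (action_sensitive && !value_estimation) {
    stop("action sensitivity requires value-based behavior estimation")
  }
  if (kalman && sensory_noise == "none") {
    stop("Kalman filtering requires sensory noise")
  }
  structure(list(value_scheme = value_scheme,
                 obs_estimation = isTRUE(obs_estimation),
                 value_estimation = isTRUE(value_estimation),
                 action_sensitive = isTRUE(action_sensitive),
                 value_noise = isTRUE(value_noise),
                 sensory_noise = sensory_noise, kalman = isTRUE(kalman),
                 accumulation = isTRUE(accumulation),
                 looming = isTRUE(looming)),
            class = "crossim_variant")
}

#' Is a variant fully deterministic?
#'
#' @param variant a [model_variant()]
#' @return logical
#' @export
is_deterministic_variant <- function(variant) {
  !variant$value_noise && variant$sensory_noise == "none"
}

#' The maximally successful model variant
#'
#' Affordance-based valuation with observation-based and action-sensitive
#' value-based behavior estimation, constant sensory noise with Kalman
#' filtering, and evidence accumulation.
#'
#' @return a [model_variant()]
#' @export
variant_max_successful <- function() {
  model_variant("affordance", obs_estimation = TRUE, value_estimation = TRUE,
                action_sensitive = TRUE, sensory_noise = "constant",
                kalman = TRUE, accumulation = TRUE)
}

#' The canonical deterministic variant lattice
#'
#' The affordance-based value scheme combined with the six behavior
#' estimation combinations: observation on/off crossed with value-based
#' estimation off / on / on-and-action-sensitive.
#'
#' @return named list of [model_variant()]
#' @export
list_deterministic_variants <- function() {
  out <- list()
  for (obs in c(FALSE, TRUE)) {
    for (val in c("off", "on", "as")) {
      nm <- paste0("affordance", if (obs) "+obs" else "",
                   switch(val, off = "", on = "+value", as = "+value_as"))
      out[[nm]] <- model_variant("affordance", obs_estimation = obs,
                                 value_estimation = val != "off",
                                 action_sensitive = val == "as")
    }
  }
  out
}

#' The canonical simple stochastic variant lattice
#'
#' Constant sensory noise crossed with Kalman filtering on/off and evidence
#' accumulation on/off, on the simplest affordance-based model.
#'
#' @return named list of [model_variant()]
#' @export
list_stochastic_variants <- function() {
  out <- list()
  for (kal in c(FALSE, TRUE)) {
    for (acc in c(FALSE, TRUE)) {
      nm <- paste0("sens", if (kal) "+kalman" else "",
                   if (acc) "+accum" else "")
      out[[nm]] <- model_variant("affordance", sensory_noise = "constant",
                                 kalman = kal, accumulation = acc)
    }
  }
  out
}

#' Combine a deterministic and a stochastic variant
#'
#' @param det a deterministic [model_variant()]
#' @param stoch a stochastic [model_variant()]
#' @return the combined [model_variant()]
#' @export
combine_variants <- function(det, stoch) {
  model_variant(det$value_scheme,
                obs_estimation = det$obs_estimation || stoch$obs_estimation,
                value_estimation = det$value_estimation ||
                  stoch$value_estimation,
                action_sensitive = det$action_sensitive ||
                  stoch$action_sensitive,
                value_noise = det$value_noise || stoch$value_noise,
                sensory_noise = if (stoch$sensory_noise != "none") {
                  stoch$sensory_noise
                } else det$sensory_noise,
                kalman = det$kalman || stoch$kalman,
                accumulation = det$accumulation || stoch$accumulation,
                looming = det$looming || stoch$looming)
}

#' Free parameters exposed by a variant
#'
#' @param variant a [model_variant()]
#' @return character vector of free parameter names
#' @export
free_parameters <- function(variant) {
  p <- "delta_V_th"
  if (variant$value_scheme == "short_term") {
    p <- c(p, "collision_cost", "priority_cost")
  } else {
    p <- c(p, "discount_T", "priority_cost")
  }
  if (variant$value_estimation) p <- c(p, "beta_V")
  if (variant$obs_estimation) p <- c(p, "sigma_O")
  if (variant$value_noise) p <- c(p, "sigma_V")
  if (variant$sensory_noise == "constant") p <- c(p, "sigma_s")
  if (variant$sensory_noise == "distance_scaled") p <- c(p, "sigma_theta")
  if (variant$kalman) p <- c(p, "process_noise_accel")
  if (variant$accumulation) p <- c(p, "T")
  if (variant$looming) p <- c(p, "looming_weight")
  p
}

#' Default free-parameter ranges for the model-selection grids
#'
#' Log-spaced grids are drawn within these ranges.  The ranges are chosen to
#' bracket the plausible human scales of each quantity: sub-second to
#' two-second accumulation, selection thresholds from near-zero to the full
#' squashed-value span, discounting from a few seconds to half a minute,
#' observation noise from centimetres to metres.
#'
#' @return named list of `c(lower, upper)` ranges
#' @export
default_parameter_ranges <- function() {
  list(
    delta_V_th = c(0.005, 0.5),
    T = c(0.15, 2),
    sigma_V = c(0.01, 1),
    beta_V = c(0.5, 20),
    sigma_O = c(0.05, 2),
    collision_cost = c(0.5, 10),
    priority_cost = c(0.5, 20),
    discount_T = c(2, 30),
    sigma_s = c(0.1, 10),
    sigma_theta = c(5e-4, 0.02),
    process_noise_accel = c(0.1, 5),
    looming_weight = c(1, 50)
  )
}

#' Default values of all model parameters
#'
#' Non-free parameters keep these values during screens; free parameters use
#' them in direct simulation calls unless overridden.
#'
#' @param role `"pedestrian"` or `"driver"` (sets the perceptual priors
#'   about the other agent)
#' @return named list
#' @export
default_params <- function(role = c("pedestrian", "driver")) {
  role <- match.arg(role)
  other_is_driver <- role == "pedestrian"
  list(
    T = 0.4, sigma_V = 0.1, delta_V_th = 0.005, beta_V = 2, sigma_O = 0.5,
    T_Of = 2, T_O1 = 0.2, sigma_s = 0.5, sigma_theta = 0.005,
    speed_est_window = 0.5, entry_margin = 1.5,
    eye_height = 1.6, noise_floor_dist = 0.5, process_noise_accel = 1,
    prior_speed_mean = if (other_is_driver) 13.4 else 1.5,
    prior_speed_sd = if (other_is_driver) 4 else 0.5,
    discount_T = 10, collision_cost = NA_real_, priority_cost = 2,
    looming_weight = 10, squash_scale = NA_real_, T_P = 0.5, ramp_dur = 0.4,
    dt_int = 0.1, reset_on_action = TRUE
  )
}
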