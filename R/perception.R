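# Perception of the other agent: Gaussian position noise (constant or
# growing with distance through the visual angle under the horizon), a
# two-state Kalman filter over position and speed, and posterior sampling.

#' Sensory noise model
#'
#' @param mode `"none"`, `"constant"` (position noise of fixed sd `sigma_s`)
#'   or `"distance_scaled"` (constant angular noise `sigma_theta` on the
#'   visual angle under the horizon, mapped to position noise
#'   sigma_x = sigma_theta (D^2 + h^2) / h at distance D and eye height h)
#' @param sigma_s constant position noise sd, m
#' @param sigma_theta retinal angular noise sd, rad
#' @param eye_height observer eye height, m
#' @param floor_dist distance floor used when the true distance is
#'   non-positive, m
#' @return object of class `crossim_noise`
#' @export
noise_model <- function(mode = c("none", "constant", "distance_scaled"),
                        sigma_s = 0.5, sigma_theta = 0.005, eye_height = 1.6,
                        floor_dist = 0.5) {
  mode <- match.arg(mode)
  stopifnot(sigma_s >= 0, sigma_theta >= 0, floor_dist > 0)
  if (mode == "distance_scaled" && eye_height <= 0) {
    stop("distance_scaled noise requires a positive eye height")
  }
  structure(list(mode = mode, sigma_s = sigma_s, sigma_theta = sigma_theta,
                 eye_height = eye_height, floor_dist = floor_dist),
            class = "crossim_noise")
}

#' Position observation noise sd at a given distance
#'
#' @param noise a [noise_model()]
#' @param distance true distance to the observed agent, m (vectorized)
#' @return observation sd, m
#' @export
noise_sd <- function(noise, distance) {
  switch(noise$mode,
         none = rep(0, length(distance)),
         constant = rep(noise$sigma_s, length(distance)),
         distance_scaled = {
           D <- pmax(distance, noise$floor_dist)
           noise$sigma_theta * (D^2 + noise$eye_height^2) / noise$eye_height
         })
}

#' Observe the other agent's position with sensory noise
#'
#' @param true_other a [kinematic_state()] of the observed agent (its
#'   `dist_to_conflict` is the observed coordinate)
#' @param noise a [noise_model()]
#' @param n number of independent observations
#' @return observed position(s), m; uses the R random number generator
#' @export
observe_position <- function(true_other, noise, n = 1) {
  d <- true_other$dist_to_conflict
  sx <- noise_sd(noise, d)
  d + stats::rnorm(n, 0, sx)
}

#' Kalman belief about the other agent's position and speed
#'
#' @param mean length-2 vector: position (m) and approach speed (m/s)
#' @param cov 2x2 covariance matrix
#' @param process_noise_accel sd of the white-acceleration process noise,
#'   m/s^2
#' @return object of class `crossim_belief`
#' @export
kalman_belief <- function(mean, cov, process_noise_accel = 1) {
  cov <- as.matrix(cov)
  stopifnot(length(mean) == 2, all(dim(cov) == c(2, 2)),
            process_noise_accel >= 0)
  if (abs(cov[1, 2] - cov[2, 1]) > 1e-8 * (1 + abs(cov[1, 2]))) {
    stop("covariance must be symmetric")
  }
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("covariance must be positive semi-definite")
  }
  structure(list(mean = as.numeric(mean), cov = cov,
                 process_noise_accel = process_noise_accel),
            class = "crossim_belief")
}

#' One Kalman predict + update step
#'
#' The state is (position, approach speed) with constant-speed transition
#' (position decreases at the approach speed) and a white-acceleration
#' process noise; the measurement is the position alone.  A non-finite
#' observation propagates the belief by prediction only.
#'
#' @param belief a [kalman_belief()]
#' @param observation observed position, m
#' @param dt time step, s
#' @param sigma_obs measurement sd, m
#' @return updated [kalman_belief()]
#' @export
kalman_step <- function(belief, observation, dt, sigma_obs) {
  stopifnot(dt > 0, sigma_obs >= 0)
  FF <- matrix(c(1, 0, -dt, 1), 2, 2)
  q <- belief$process_noise_accel^2
  Q <- q * matrix(c(dt^4 / 4, -dt^3 / 2, -dt^3 / 2, dt^2), 2, 2)
  m <- as.numeric(FF %*% belief$mean)
  P <- FF %*% belief$cov %*% t(FF) + Q
  if (is.finite(observation)) {
    S <- P[1, 1] + sigma_obs^2
    K <- P[, 1] / S
    innov <- observation - m[1]
    m <- m + K * innov
    P <- P - K %o% P[1, ]
    P <- (P + t(P)) / 2
  }
  kalman_belief(m, P, belief$process_noise_accel)
}

#' Draw a percept from the Kalman posterior
#'
#' The agent's percept carries its own state exactly, and a joint draw of
#' the other agent's position and speed from the full posterior Gaussian.
#'
#' @param belief a [kalman_belief()]
#' @param ego the agent's own [kinematic_state()]
#' @return object of class `crossim_percept` with fields `ego`,
#'   `other_position`, `other_speed`; uses the R random number generator
#' @export
draw_percept <- function(belief, ego) {
  P <- belief$cov
  l00 <- sqrt(max(P[1, 1], 0))
  l10 <- if (l00 > 1e-12) P[2, 1] / l00 else 0
  l11 <- sqrt(max(P[2, 2] - l10^2, 0))
  z <- stats::rnorm(2)
  structure(list(ego = ego,
                 other_position = belief$mean[1] + l00 * z[1],
                 other_speed = belief$mean[2] + l10 * z[1] + l11 * z[2]),
            class = "crossim_percept")
}
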