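# Simulation engine wrappers: build the per-agent configuration for the
# compiled per-step loop, run one- and two-agent episodes, and assemble tidy
# traces.

sens_mode_index <- function(mode) {
  match(mode, c("none", "constant", "distance_scaled")) - 1L
}

# full engine parameter list for one modeled agent
resolve_params <- function(role, variant, params = list()) {
  p <- modifyList(default_params(role), as.list(params))
  if (is.na(p$squash_scale)) {
    p$squash_scale <- if (variant$value_scheme == "short_term") {
      1
    } else {
      1 / p$discount_T
    }
  }
  if (is.na(p$collision_cost)) {
    # short-term scheme: a one-shot payoff deduction on a collision course;
    # affordance scheme: a cost *rate* during predicted simultaneous
    # occupancy, severe relative to the unit progress-reward rate
    p$collision_cost <- if (variant$value_scheme == "short_term") 5 else 30
  }
  if (!variant$looming) p$looming_weight <- 0
  p
}

build_agent_cfg <- function(role, spec, variant, params, action_set = NULL,
                            reward = NULL) {
  other_role <- if (role == "pedestrian") "driver" else "pedestrian"
  st <- spec$initial_states[[role]]
  zone_self <- zone_length(spec$geometry, role)
  zone_other <- zone_length(spec$geometry, other_role)
  p <- resolve_params(role, variant, params)
  if (is.null(action_set)) action_set <- default_action_set(role)
  if (is.null(reward)) reward <- default_reward_params(role)
  reward_oth <- default_reward_params(other_role)
  is_driver <- role == "driver"

  mk_valcfg <- function(ego_is_self) {
    list(scheme = match(variant$value_scheme,
                        c("short_term", "affordance")) - 1L,
         sigmoid = 0L, T_P = p$T_P, discount_T = p$discount_T,
         collision_cost = p$collision_cost, priority_cost = p$priority_cost,
         looming_weight = p$looming_weight, squash_scale = p$squash_scale,
         dt_int = p$dt_int,
         a_comf = unname(plan_bounds(if (ego_is_self) role else other_role)[["a_comf"]]),
         a_max = unname(plan_bounds(if (ego_is_self) role else other_role)[["a_max"]]),
         a_dec_max = unname(plan_bounds(if (ego_is_self) role else other_role)[["a_dec_max"]]),
         zone_ego = if (ego_is_self) zone_self else zone_other,
         zone_oth = if (ego_is_self) zone_other else zone_self,
         margin_ego = if (xor(ego_is_self, !is_driver)) p$entry_margin else 0,
         margin_oth = if (xor(ego_is_self, !is_driver)) 0 else p$entry_margin,
         oth_has_priority = if (ego_is_self) {
           spec$ped_priority && is_driver
         } else {
           spec$ped_priority && !is_driver
         },
         block_first = FALSE)
  }

  list(modeled = TRUE,
       role = if (is_driver) 1L else 0L,
       zone = zone_self,
       d0 = st$dist_to_conflict, v0 = st$speed,
       baseline = if (is_driver) 0 else st$speed,
       amps = action_set$amplitude,
       reward = reward_cpp(reward),
       other_reward = reward_cpp(reward_oth),
       valcfg = mk_valcfg(TRUE),
       valcfg_oth = mk_valcfg(FALSE),
       proj_other = behavior_projection(other_role),
       flags = list(obs_estimation = variant$obs_estimation,
                    value_estimation = variant$value_estimation,
                    action_sensitive = variant$action_sensitive,
                    value_noise = variant$value_noise,
                    sensory_mode = sens_mode_index(variant$sensory_noise),
                    kalman = variant$kalman,
                    accumulation = variant$accumulation),
       params = p,
       v_free = reward$v_free)
}

build_scripted_cfg <- function(role, spec, times) {
  st <- scripted_state(spec, role, times)
  list(modeled = FALSE,
       role = if (role == "driver") 1L else 0L,
       zone = zone_length(spec$geometry, role),
       d0 = st$dist_to_conflict[1], v0 = st$speed[1],
       d = st$dist_to_conflict, v = st$speed)
}

assemble_trace <- function(res, spec, seed, v_free) {
  out <- list()
  for (i in 1:2) {
    role <- c("pedestrian", "driver")[i]
    m <- res[[i]]
    df <- as.data.frame(m)
    df$role <- role
    df$modeled <- role %in% spec$modeled_roles
    out[[i]] <- df
  }
  tr <- rbind(out[[1]], out[[2]])
  tr <- tr[order(tr$t, tr$role), ]
  rownames(tr) <- NULL
  attr(tr, "spec") <- spec
  attr(tr, "seed") <- seed
  attr(tr, "v_free") <- v_free
  class(tr) <- c("crossim_trace", class(tr))
  tr
}

run_spec <- function(spec, variants, params_by_role, seed) {
  n_steps <- round(spec$duration / spec$dt)
  times <- seq(0, by = spec$dt, length.out = n_steps + 1)
  agents <- list()
  v_free <- c(pedestrian = NA_real_, driver = NA_real_)
  for (role in c("pedestrian", "driver")) {
    if (role %in% spec$modeled_roles) {
      cfga <- build_agent_cfg(role, spec, variants[[role]],
                              params_by_role[[role]])
      v_free[[role]] <- cfga$v_free
      agents[[length(agents) + 1]] <- cfga
    } else {
      agents[[length(agents) + 1]] <- build_scripted_cfg(role, spec, times)
      v_free[[role]] <- spec$scripts[[role]]$v0
    }
  }
  cfg <- list(dt = spec$dt, n_steps = as.integer(n_steps),
              seed = as.double(seed %% 2^31),
              ped_priority = spec$ped_priority, agents = agents)
  if (!is.null(spec$lead)) {
    lst <- script_state_at(spec$lead$script,
                           spec$lead$state$dist_to_conflict, times)
    cfg$lead_d <- lst$dist_to_conflict
    cfg$lead_zone <- zone_length(spec$geometry, "driver")
  }
  res <- cpp_run_sim(cfg)
  assemble_trace(res, spec, seed, v_free)
}

#' Simulate one scenario with a single model-controlled agent
#'
#' The scripted agent follows its profile exactly; the modeled agent runs
#' the full perceive - estimate - value - accumulate - select loop each
#' step.  All stochastic draws derive from per-subsystem streams seeded
#' from `seed`, so deterministic variants produce identical traces for any
#' seed and repeated calls are exactly reproducible.
#'
#' @param spec a [scenario_spec()] with exactly one modeled role
#' @param variant a [model_variant()]
#' @param params named list of parameter overrides (see [default_params()])
#' @param seed integer run seed
#' @return a tidy trace data.frame (one row per step per agent) of class
#'   `crossim_trace`, with the scenario, seed and free-speed metadata
#'   attached as attributes
#' @export
run_single_agent <- function(spec, variant, params = list(), seed = 1) {
  if (length(spec$modeled_roles) != 1) {
    stop("spec must have exactly one modeled role")
  }
  role <- spec$modeled_roles
  variants <- setNames(list(variant), role)
  run_spec(spec, variants, setNames(list(params), role), seed)
}

#' Simulate one scenario with both agents model-controlled
#'
#' Both agents update synchronously: each acts on the other's state from the
#' previous step, so the update order of the two agents cannot affect the
#' result.
#'
#' @param spec a [scenario_spec()] with both roles modeled
#' @param variant a [model_variant()] used for both agents (or a list with
#'   entries `pedestrian` and `driver`)
#' @param params_ped,params_drv parameter overrides per role
#' @param seed integer run seed
#' @return a `crossim_trace` as in [run_single_agent()]
#' @export
run_two_agents <- function(spec, variant, params_ped = list(),
                           params_drv = list(), seed = 1) {
  if (!setequal(spec$modeled_roles, c("pedestrian", "driver"))) {
    stop("spec must have both roles modeled")
  }
  if (inherits(variant, "crossim_variant")) {
    variants <- list(pedestrian = variant, driver = variant)
  } else {
    variants <- variant
  }
  run_spec(spec, variants,
           list(pedestrian = params_ped, driver = params_drv), seed)
}

#' Deterministic per-stream normal draws used by the engine
#'
#' Exposes the engine's per-(agent, subsystem) random streams, mainly so
#' that engine runs can be replicated step by step outside the compiled
#' loop.  Subsystems: 0 sensory noise, 1 Kalman posterior draws, 2 action
#' value noise, 3 behavior value noise.
#'
#' @param seed run seed
#' @param agent agent index (0 pedestrian, 1 driver)
#' @param subsystem subsystem index
#' @param n number of draws
#' @return numeric vector of standard normal draws
#' @export
engine_stream_normals <- function(seed, agent, subsystem, n) {
  cpp_rng_normals(as.double(seed %% 2^31), as.integer(agent),
                  as.integer(subsystem), as.integer(n))
}
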