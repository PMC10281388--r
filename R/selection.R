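# Model selection: parameter grids, the deterministic and stochastic
# screens, combination sampling, and the two experiment prediction
# pipelines with their design bookkeeping.

#' Logarithmically spaced parameter grid
#'
#' @param ranges named list of `c(lower, upper)` ranges (all positive)
#' @param n_per_param grid points per parameter; `n_per_param = 1` uses the
#'   geometric midpoint of each range
#' @return data.frame, one row per parameterization (full Cartesian grid)
#' @export
parameter_grid <- function(ranges, n_per_param = 10) {
  stopifnot(length(ranges) >= 1, n_per_param >= 1)
  vals <- lapply(ranges, function(r) {
    if (any(r <= 0)) stop("log spacing requires positive range bounds")
    if (n_per_param == 1) {
      sqrt(r[1] * r[2])
    } else {
      exp(seq(log(r[1]), log(r[2]), length.out = n_per_param))
    }
  })
  expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
}

phenomenon_of <- function(spec) spec$phenomenon

run_screen_one <- function(variant, params, scenarios, criteria, seed = 1,
                           context = "screen") {
  phens <- unique(vapply(scenarios, phenomenon_of, character(1)))
  reports <- setNames(vector("list", length(phens)), phens)
  any_collision <- FALSE
  any_nonprog <- FALSE
  for (spec in scenarios) {
    tr <- run_single_agent(spec, variant, params, seed)
    m <- compute_metrics(tr, spec, context)
    any_collision <- any_collision || m$collision
    any_nonprog <- any_nonprog || m$nonprogression
    ph <- phenomenon_of(spec)
    reports[[ph]] <- c(reports[[ph]], list(m))
  }
  flags <- phenomenon_flags(reports, criteria)
  list(flags = flags, collision = any_collision, nonprogression = any_nonprog,
       reports = reports)
}

#' Deterministic model-selection screen
#'
#' Simulates every parameterization of a deterministic variant over the
#' phenomenon scenarios (all kinematic variants), computes the behavior
#' metrics and phenomenon flags, and retains the parameterizations that
#' exhibit at least the required number of phenomena.
#'
#' @param variant a deterministic [model_variant()]
#' @param grid data.frame of free-parameter values (one row each); defaults
#'   to a log grid over [default_parameter_ranges()] for the variant's free
#'   parameters
#' @param scenarios phenomenon scenario list from
#'   [build_phenomenon_scenarios()]
#' @param criteria a [retention_criteria()]
#' @param n_per_param grid resolution when `grid` is NULL
#' @return list with `report` (one row per parameterization: free
#'   parameters, phenomenon flags, retention) and `retained` (the retained
#'   subset)
#' @export
deterministic_screen <- function(variant, grid = NULL,
                                 scenarios = build_phenomenon_scenarios(),
                                 criteria = retention_criteria(),
                                 n_per_param = 10) {
  if (!is_deterministic_variant(variant)) {
    stop("the deterministic screen requires all stochastic assumptions off")
  }
  if (is.null(grid)) {
    rng <- default_parameter_ranges()[free_parameters(variant)]
    grid <- parameter_grid(rng, n_per_param)
  }
  if (nrow(grid) == 0) {
    empty <- cbind(grid, n_phenomena = numeric(0), retained = logical(0))
    return(list(report = empty, retained = empty))
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- run_screen_one(variant, as.list(grid[i, , drop = FALSE]),
                          scenarios, criteria)
    ok <- TRUE
    if (criteria$require_collision_free && res$collision) ok <- FALSE
    if (criteria$require_progression && res$nonprogression) ok <- FALSE
    rows[[i]] <- c(as.list(grid[i, , drop = FALSE]),
                   as.list(res$flags),
                   list(n_phenomena = sum(res$flags),
                        collision = res$collision,
                        nonprogression = res$nonprogression,
                        retained = ok && sum(res$flags) >=
                          criteria$min_phenomena_deterministic))
  }
  report <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  report$param_id <- seq_len(nrow(report))
  list(report = report, retained = report[report$retained, , drop = FALSE])
}

#' Stochastic model-selection screen
#'
#' Each parameterization is simulated over repetitions of the one-agent
#' gap-acceptance scenario (base kinematic variant) and over the three
#' interactive scenarios.  Retained parameterizations exhibit gap
#' acceptance hesitation -- a bias toward slowing (median speed ratio below
#' one, distinguishing genuine hesitation from symmetric decision jitter)
#' with at least one clear hesitation episode below the threshold -- and
#' produce collision-free interactive runs.
#'
#' @param variant a stochastic [model_variant()]
#' @param parameterizations data.frame of free-parameter values
#' @param n_reps repetitions per scenario
#' @param seed base seed; each (parameterization, repetition) derives its
#'   own run seed
#' @param criteria a [retention_criteria()]
#' @param gap_scenario the one-agent gap-acceptance scenario (base variant)
#' @param interactive_scenarios the three two-agent scenarios
#' @param require_gap require the gap-hesitation flag for retention; the
#'   combined-population screen sets this to FALSE (hesitation is certified
#'   at the simple-variant stage; the combined stage guards interaction
#'   safety)
#' @return list with `report` and `retained` data.frames
#' @export
stochastic_screen <- function(variant, parameterizations, n_reps = 5,
                              seed = 1, criteria = retention_criteria(),
                              gap_scenario = NULL,
                              interactive_scenarios = build_encounter_scenarios(),
                              require_gap = TRUE) {
  if (is_deterministic_variant(variant)) {
    stop("the stochastic screen requires at least one stochastic assumption")
  }
  if (nrow(parameterizations) == 0) {
    empty <- cbind(parameterizations, gap_hesitation = logical(0),
                   collision = logical(0), retained = logical(0))
    return(list(report = empty, retained = empty))
  }
  if (is.null(gap_scenario)) {
    ph <- build_phenomenon_scenarios(dt = 0.025)
    gap_scenario <- ph[["gap_acceptance_hesitation/tta+0.0"]]
  }
  rows <- vector("list", nrow(parameterizations))
  for (i in seq_len(nrow(parameterizations))) {
    params <- as.list(parameterizations[i, , drop = FALSE])
    ratios <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      tr <- run_single_agent(gap_scenario, variant, params,
                             seed = seed + i * 1000 + r)
      ratios[r] <- compute_metrics(tr, gap_scenario)$ped_speed_ratio
    }
    gap_flag <- stats::median(ratios) < 1 &&
      any(ratios < criteria$hesitation_ratio)
    collision <- FALSE
    if (gap_flag || !require_gap) { # skip runs for already-rejected rows
      for (sc in interactive_scenarios) {
        for (r in seq_len(n_reps)) {
          tr <- run_two_agents(sc, variant, params, params,
                               seed = seed + i * 1000 + 100 + r)
          if (detect_collision_nonprogression(tr, sc, "exp2")$collision) {
            collision <- TRUE
          }
        }
        if (collision) break
      }
    }
    rows[[i]] <- c(params,
                   list(median_speed_ratio = stats::median(ratios),
                        gap_hesitation = gap_flag, collision = collision,
                        retained = (gap_flag || !require_gap) && !collision))
  }
  report <- do.call(rbind, lapply(rows, as.data.frame))
  report$param_id <- seq_len(nrow(report))
  list(report = report, retained = report[report$retained, , drop = FALSE])
}

#' Combine retained deterministic and stochastic parameterizations
#'
#' Forms every combined variant (Cartesian pairing of the deterministic and
#' stochastic variant lists) and, for each, pairs every retained
#' deterministic parameterization with every retained stochastic one,
#' sampling uniformly without replacement when the number of combinations
#' exceeds `n_sample`.
#'
#' @param det_retained named list: deterministic variant name ->
#'   data.frame of retained parameterizations
#' @param stoch_retained named list for the stochastic variants
#' @param det_variants,stoch_variants named lists of the corresponding
#'   [model_variant()] objects
#' @param n_sample maximum population size per combined variant
#' @param seed sampling seed
#' @return list with `populations` (combined variant name -> data.frame of
#'   parameter sets), `variants` (the combined [model_variant()] objects)
#'   and `n_combined_variants`
#' @export
combine_and_sample <- function(det_retained, stoch_retained, det_variants,
                               stoch_variants, n_sample = 5000, seed = 1) {
  pops <- list()
  vars <- list()
  drop_cols <- c("param_id", "retained", "collision", "nonprogression",
                 "n_phenomena", "gap_hesitation", "median_speed_ratio",
                 "priority_assertion", "short_stopping",
                 "yield_acceptance_hesitation", "early_yield_acceptance",
                 "gap_acceptance_hesitation")
  set.seed(seed %% 2^31)
  for (dn in names(det_retained)) {
    for (sn in names(stoch_retained)) {
      nm <- paste(dn, sn, sep = " x ")
      dd <- det_retained[[dn]]
      ss <- stoch_retained[[sn]]
      dd <- dd[, setdiff(names(dd), drop_cols), drop = FALSE]
      ss <- ss[, setdiff(names(ss), drop_cols), drop = FALSE]
      if (nrow(dd) == 0 || nrow(ss) == 0) {
        warning("no combined parameterizations for variant ", nm)
        pops[[nm]] <- dd[0, , drop = FALSE]
      } else {
        idx <- expand.grid(di = seq_len(nrow(dd)), si = seq_len(nrow(ss)))
        take <- min(n_sample, nrow(idx))
        pick <- idx[sample.int(nrow(idx), take), , drop = FALSE]
        # stochastic-screen values win for parameters present in both
        both <- intersect(names(dd), names(ss))
        dpart <- dd[pick$di, setdiff(names(dd), both), drop = FALSE]
        spart <- ss[pick$si, , drop = FALSE]
        pop <- cbind(dpart, spart)
        rownames(pop) <- NULL
        pops[[nm]] <- pop
      }
      vars[[nm]] <- combine_variants(det_variants[[dn]], stoch_variants[[sn]])
    }
  }
  list(populations = pops, variants = vars,
       n_combined_variants = length(pops))
}

#' Predicted crossing-initiation times for the two-vehicle experiment
#'
#' Draws parameterizations from a retained population and simulates the
#' pedestrian model in every scenario with repetitions.  While the lead
#' vehicle has not yet passed the pedestrian, the pass-first access order
#' carries value -Inf (the instruction not to cross before the first car).
#' The crossing initiation time (CIT) is measured from the lead vehicle's
#' rear passing the crossing location to pedestrian movement onset.
#' Parameterizations producing any non-progressing run are excluded.
#'
#' @param variant the [model_variant()] to test
#' @param population data.frame of parameter sets
#' @param n_draw parameterizations drawn at random
#' @param n_reps repetitions per scenario
#' @param seed base seed
#' @param scenarios scenario list from [build_exp1_scenarios()]
#' @return data.frame with one row per run: scenario descriptors, parameter
#'   id, repetition, CIT and the exclusion flag
#' @export
predict_exp1 <- function(variant, population, n_draw = 500, n_reps = 6,
                         seed = 1, scenarios = build_exp1_scenarios()) {
  if (nrow(population) == 0) {
    warning("empty parameterization population")
    return(data.frame())
  }
  set.seed(seed %% 2^31)
  take <- min(n_draw, nrow(population))
  pick <- sample.int(nrow(population), take)
  rows <- list()
  for (pi in seq_along(pick)) {
    params <- as.list(population[pick[pi], , drop = FALSE])
    excluded <- FALSE
    runs <- list()
    for (si in seq_along(scenarios)) {
      spec <- scenarios[[si]]
      for (r in seq_len(n_reps)) {
        tr <- run_single_agent(spec, variant, params,
                               seed = seed + pi * 10000 + si * 100 + r)
        m <- compute_metrics(tr, spec, "exp1")
        if (m$nonprogression) excluded <- TRUE
        runs[[length(runs) + 1]] <- data.frame(
          scenario = spec$name, speed = spec$meta$speed,
          gap = spec$meta$gap, yielding = spec$meta$yielding,
          param = pi, rep = r, cit = m$crossing_initiation_time,
          nonprogression = m$nonprogression)
      }
    }
    runs <- do.call(rbind, runs)
    runs$excluded <- excluded
    rows[[pi]] <- runs
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predicted interaction outcomes for the interactive experiment
#'
#' Draws parameterizations and runs two-agent simulations of every scenario
#' (time gap x priority), recording who enters the conflict space first.
#' Runs flagged as non-progressing (either agent failing to enter within
#' 20 s) are excluded.
#'
#' @inheritParams predict_exp1
#' @param scenarios scenario list from [build_exp2_scenarios()]
#' @return data.frame with one row per run
#' @export
predict_exp2 <- function(variant, population, n_draw = 500, seed = 1,
                         scenarios = build_exp2_scenarios()) {
  if (nrow(population) == 0) {
    warning("empty parameterization population")
    return(data.frame())
  }
  set.seed(seed %% 2^31)
  take <- min(n_draw, nrow(population))
  pick <- sample.int(nrow(population), take)
  rows <- list()
  for (pi in seq_along(pick)) {
    params <- as.list(population[pick[pi], , drop = FALSE])
    for (si in seq_along(scenarios)) {
      spec <- scenarios[[si]]
      tr <- run_two_agents(spec, variant, params, params,
                           seed = seed + pi * 10000 + si * 100)
      m <- compute_metrics(tr, spec, "exp2")
      rows[[length(rows) + 1]] <- data.frame(
        scenario = spec$name, gap = spec$meta$gap,
        priority = spec$meta$priority, param = pi, outcome = m$outcome,
        collision = m$collision, nonprogression = m$nonprogression)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Outcome proportion table for the interactive experiment predictions
#'
#' @param runs output of [predict_exp2()]
#' @return data.frame with `gap`, `priority`, `n` and `p_ped_first`
#'   (non-progressing runs excluded)
#' @export
summarize_exp2 <- function(runs) {
  ok <- runs[!runs$nonprogression, , drop = FALSE]
  if (nrow(ok) == 0) {
    warning("all runs excluded as non-progressing")
    return(data.frame(gap = numeric(0), priority = logical(0),
                      n = integer(0), p_ped_first = numeric(0)))
  }
  agg <- aggregate(list(p_ped_first = ok$outcome == "ped_first",
                        n = rep(1L, nrow(ok))),
                   by = list(gap = ok$gap, priority = ok$priority),
                   FUN = function(x) sum(as.numeric(x)))
  agg$p_ped_first <- agg$p_ped_first / agg$n
  agg[order(agg$priority, agg$gap), ]
}

#' Bimodality check for crossing-initiation-time distributions
#'
#' Histograms the CITs with fixed bin width and reports bimodality when at
#' least two local maxima are separated by a trough lower than the given
#' fraction of the smaller peak.  Maxima holding less than `min_peak_frac`
#' of the observations are not counted as modes (stray single observations
#' in otherwise empty bins are noise, not a crossing mode).
#'
#' @param cit crossing initiation times, s (NAs dropped)
#' @param bin_width histogram bin width, s
#' @param trough_frac trough threshold as a fraction of the smaller peak
#' @param min_peak_frac minimum share of observations a mode must hold
#' @return list with `bimodal`, the bin `counts` and the detected `peaks`
#' @export
cit_bimodality <- function(cit, bin_width = 0.5, trough_frac = 0.5,
                           min_peak_frac = 0.05) {
  cit <- cit[is.finite(cit)]
  if (length(cit) < 10) {
    return(list(bimodal = FALSE, counts = integer(0), peaks = integer(0)))
  }
  br <- seq(floor(min(cit) / bin_width) * bin_width,
            ceiling(max(cit) / bin_width) * bin_width + bin_width,
            by = bin_width)
  counts <- as.integer(table(cut(cit, br, right = FALSE)))
  n <- length(counts)
  pad <- c(-1L, counts, -1L)
  peaks <- which(counts > pad[seq_len(n)] & counts >= pad[seq_len(n) + 2])
  peaks <- peaks[counts[peaks] >= min_peak_frac * length(cit)]
  bimodal <- FALSE
  if (length(peaks) >= 2) {
    for (i in seq_len(length(peaks) - 1)) {
      a <- peaks[i]
      b <- peaks[i + 1]
      trough <- min(counts[a:b])
      if (trough < trough_frac * min(counts[a], counts[b])) bimodal <- TRUE
    }
  }
  list(bimodal = bimodal, counts = counts, peaks = peaks)
}

# ---------------------------------------------------------------------------
# design bookkeeping
# ---------------------------------------------------------------------------

#' Trial ledger of the two-vehicle crossing experiment
#'
#' Participants experienced blocks of two repetitions of each kinematic
#' scenario variation; for a subset of participants half of the yielding
#' trials carried a vehicle signaling interface and are excluded here.
#'
#' @param n_participants total participants
#' @param n_blocks experimental blocks per participant
#' @param n_speeds,n_gaps,n_behaviors design factors (speeds x gaps x
#'   second-vehicle behaviors)
#' @param reps repetitions of each scenario per block
#' @param n_ehmi_participants participants for whom half of the yielding
#'   trials are excluded
#' @return list with `n_scenarios`, `trials_per_block`,
#'   `included_per_block_ehmi` and `total_trials`
#' @export
exp1_trial_ledger <- function(n_participants = 60, n_blocks = 3,
                              n_speeds = 3, n_gaps = 4, n_behaviors = 2,
                              reps = 2, n_ehmi_participants = 40) {
  n_scenarios <- n_speeds * n_gaps * n_behaviors
  per_block <- n_scenarios * reps
  yielding_per_block <- n_speeds * n_gaps * reps
  included_ehmi <- per_block - yielding_per_block / 2
  total <- n_blocks * ((n_participants - n_ehmi_participants) * per_block +
                         n_ehmi_participants * included_ehmi)
  list(n_scenarios = n_scenarios, trials_per_block = per_block,
       included_per_block_ehmi = included_ehmi, total_trials = total)
}

#' Trial ledger of the interactive crossing experiment
#'
#' @param n_pairs participant pairs
#' @param n_blocks blocks per pair
#' @param n_gaps,n_priority design factors
#' @param reps repetitions of each scenario per block
#' @return list with `n_scenarios`, `trials_per_block` and `total_trials`
#' @export
exp2_trial_ledger <- function(n_pairs = 32, n_blocks = 2, n_gaps = 5,
                              n_priority = 2, reps = 2) {
  n_scenarios <- n_gaps * n_priority
  per_block <- n_scenarios * reps
  list(n_scenarios = n_scenarios, trials_per_block = per_block,
       total_trials = n_pairs * n_blocks * per_block)
}
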