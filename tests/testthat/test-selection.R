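test_that("parameter grids are log-spaced Cartesian products", {
  g <- parameter_grid(list(a = c(0.1, 10)), n_per_param = 10)
  expect_equal(g$a[1], 0.1)
  expect_equal(g$a[10], 10)
  r <- g$a[-1] / head(g$a, -1)
  expect_lt(diff(range(r)), 1e-12)
  g2 <- parameter_grid(list(a = c(0.1, 10), b = c(1, 2)), n_per_param = 10)
  expect_equal(nrow(g2), 100)
  g3 <- parameter_grid(list(a = c(0.1, 10)), n_per_param = 1)
  expect_equal(g3$a, 1)
  expect_error(parameter_grid(list(a = c(0, 1))), "positive")
})

test_that("trial ledgers reproduce the experimental bookkeeping", {
  l1 <- exp1_trial_ledger()
  expect_equal(l1$n_scenarios, 24)
  expect_equal(l1$trials_per_block, 48)
  expect_equal(l1$total_trials, 7200)
  expect_equal(l1$total_trials, 3 * (20 * 48 + 40 * 36))
  l2 <- exp2_trial_ledger()
  expect_equal(l2$n_scenarios, 10)
  expect_equal(l2$trials_per_block, 20)
  expect_equal(l2$total_trials, 1280)
})

test_that("combination sampling pairs retained parameterizations", {
  det <- list(v1 = data.frame(delta_V_th = c(0.01, 0.02), priority_cost = 1),
              v2 = data.frame(delta_V_th = 0.05, priority_cost = 2))
  sto <- list(s1 = data.frame(sigma_s = c(1, 2, 3), delta_V_th = 0.1))
  dv <- list(v1 = model_variant("affordance", value_estimation = TRUE),
             v2 = model_variant("affordance", obs_estimation = TRUE))
  sv <- list(s1 = model_variant("affordance", sensory_noise = "constant"))
  res <- combine_and_sample(det, sto, dv, sv, n_sample = 4, seed = 2)
  expect_equal(res$n_combined_variants, 2)
  expect_equal(nrow(res$populations[["v1 x s1"]]), min(4, 2 * 3))
  expect_equal(nrow(res$populations[["v2 x s1"]]), 3)
  # stochastic-screen values win for shared parameters
  expect_true(all(res$populations[["v1 x s1"]]$delta_V_th == 0.1))
  # combined variants inherit both assumption sets
  expect_true(res$variants[["v1 x s1"]]$value_estimation)
  expect_equal(res$variants[["v1 x s1"]]$sensory_noise, "constant")
  # reproducible sampling
  res2 <- combine_and_sample(det, sto, dv, sv, n_sample = 4, seed = 2)
  expect_identical(res$populations, res2$populations)
  # empty inputs warn and yield empty populations
  expect_warning(
    combine_and_sample(list(v1 = det$v1[0, ]), sto, dv["v1"], sv,
                       n_sample = 4),
    "no combined")
})

test_that("the canonical variant lattices have the documented sizes", {
  expect_length(list_deterministic_variants(), 6)
  expect_length(list_stochastic_variants(), 4)
  expect_true(all(vapply(list_deterministic_variants(),
                         is_deterministic_variant, logical(1))))
  expect_false(any(vapply(list_stochastic_variants(),
                          is_deterministic_variant, logical(1))))
  v <- variant_max_successful()
  expect_true(v$kalman && v$accumulation && v$action_sensitive &&
                v$obs_estimation)
})

test_that("variant dependency constraints are enforced", {
  expect_error(model_variant("affordance", action_sensitive = TRUE),
               "value-based")
  expect_error(model_variant("affordance", kalman = TRUE), "sensory noise")
  expect_setequal(
    free_parameters(model_variant("short_term")),
    c("delta_V_th", "collision_cost", "priority_cost"))
  expect_true("process_noise_accel" %in%
                free_parameters(variant_max_successful()))
})

test_that("the bimodality detector separates one- and two-mode samples", {
  set.seed(4)
  uni <- rnorm(200, 2, 0.3)
  expect_false(cit_bimodality(uni)$bimodal)
  bi <- c(rnorm(100, 0.5, 0.2), rnorm(100, 7, 0.4))
  expect_true(cit_bimodality(bi)$bimodal)
  expect_false(cit_bimodality(c(1, 2, 3))$bimodal) # too few observations
})

test_that("outcome tables summarize interactive runs", {
  runs <- data.frame(
    gap = rep(c(3, 5), each = 4),
    priority = rep(c(TRUE, FALSE), 4),
    outcome = c("ped_first", "veh_first", "ped_first", "ped_first",
                "ped_first", "ped_first", "veh_first", "ped_first"),
    nonprogression = c(rep(FALSE, 7), TRUE))
  tab <- summarize_exp2(runs)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$n[tab$gap == 5 & !tab$priority], 1)
  row <- tab[tab$gap == 3 & tab$priority, ]
  expect_equal(row$p_ped_first, 1)
})

test_that("screens validate their variant class", {
  expect_error(deterministic_screen(variant_max_successful()),
               "stochastic assumptions off")
  expect_error(stochastic_screen(model_variant("affordance"),
                                 data.frame(delta_V_th = 0.01)),
               "stochastic assumption")
})
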