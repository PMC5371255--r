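test_that("distribution assignment matches the stated sampling rules", {
  set.seed(11)
  unif <- assign_distribution(parameter_spec(
    "attrib", 0.13, 0.018, 0.165, distribution = "uniform_range"))(2e4)
  expect_gte(min(unif), 0.018)
  expect_lte(max(unif), 0.165)
  expect_equal(mean(unif), (0.018 + 0.165) / 2, tolerance = 0.01)

  norm <- assign_distribution(parameter_spec(
    "lfp", 4.6, 0.9, 8.3, distribution = "normal_ci", se = 1.88))(2e4)
  expect_equal(mean(norm), 4.6, tolerance = 0.01)
  expect_equal(sd(norm), 1.88, tolerance = 0.02)

  cost <- assign_distribution(parameter_spec(
    "fixed", 32, 22.4, 46.6, distribution = "right_skewed_cost"))(2e4)
  expect_equal(median(cost), 32, tolerance = 0.01)
  expect_equal(mean(cost > 46.6) + mean(cost < 22.4), 0.05,
               tolerance = 0.2)
  expect_gt(mean(cost), median(cost))  # right-skewed

  fixed <- assign_distribution(parameter_spec("k", 7))(100)
  expect_equal(fixed, rep(7, 100))
  expect_error(assign_distribution(parameter_spec(
    "bad", 1, 0, 2, distribution = "right_skewed_cost")),
    "unsupported-distribution")
})

test_that("joint draws are clamped to their valid domains", {
  set.seed(2)
  wide <- list(parameter_spec("delta_abstinence", 0.9, 0.4, 1,
                              distribution = "normal_ci", se = 0.5),
               parameter_spec("house_wage", 0.1, 0.05, 0.2,
                              distribution = "normal_ci", se = 0.4))
  d <- draw_parameters(wide, 5000)
  expect_true(all(d$delta_abstinence >= 0 & d$delta_abstinence <= 1))
  expect_true(all(d$house_wage >= 0))
  expect_gt(max(d$house_wage), 1)  # wages are not capped at 1
  clamps <- attr(d, "clamp_counts")
  expect_true(all(clamps > 0))
})

test_that("the PSA is bit-identical under the same seed", {
  cfg <- psa_config(n_reps = 300, effect_lengths = c(1, 2), seed = 99)
  a <- run_psa(cfg, base_inputs(), base_specs, keep_draws = TRUE)
  b <- run_psa(cfg, base_inputs(), base_specs, keep_draws = TRUE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "draws"), attr(b, "draws"))
  c_ <- run_psa(psa_config(n_reps = 300, effect_lengths = c(1, 2),
                           seed = 100), base_inputs(), base_specs)
  expect_false(identical(a$mean_bcr, c_$mean_bcr))
})

test_that("degenerate samplers collapse the PSA onto the base case", {
  fixed_specs <- lapply(base_specs, function(s)
    parameter_spec(s$name, s$base, distribution = "fixed"))
  # the composite bases at full precision, as the deterministic model uses
  fixed_specs$delta_abstinence$base <- base_params_fixture$delta_abstinence
  fixed_specs$adherence_gain$base <- base_params_fixture$adherence_gain
  res <- run_psa(psa_config(n_reps = 50, effect_lengths = 2, seed = 5),
                 base_inputs(), fixed_specs)
  det <- evaluate_model(base_inputs())$bcr
  expect_equal(res$mean_bcr, det, tolerance = 1e-12)
  expect_equal(res$ci_high - res$ci_low, 0)
})

test_that("a single replicate yields a degenerate summary", {
  res <- run_psa(psa_config(n_reps = 1, effect_lengths = 2, seed = 8),
                 base_inputs(), base_specs)
  expect_equal(res$ci_low, res$mean_bcr)
  expect_equal(res$ci_high, res$mean_bcr)
  expect_equal(res$ci_mean_low, res$mean_bcr)
})

test_that("PSA summary intervals bracket the mean", {
  res <- run_psa(psa_config(n_reps = 1000, seed = 21), base_inputs(),
                 base_specs)
  expect_true(all(res$ci_low <= res$mean_bcr))
  expect_true(all(res$mean_bcr <= res$ci_high))
  expect_true(all(diff(res$mean_bcr) > 0))  # longer effects, larger BCR
})

test_that("the Monte Carlo standard error shrinks as 1/sqrt(n)", {
  ses <- vapply(c(100, 400, 1600), function(n) {
    r <- run_psa(psa_config(n_reps = n, effect_lengths = 2, seed = 31),
                 base_inputs(), base_specs)
    (r$ci_mean_high - r$ci_mean_low) / 2
  }, 0)
  expect_true(all(diff(ses) < 0))
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.35)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.35)
})
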