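test_that("abstinence effect is the difference of the two arm rates", {
  expect_equal(derive_abstinence_effect(0.69, 0.38), 0.31)
  expect_equal(derive_abstinence_effect(0.5, 0.5), 0)
  expect_equal(derive_abstinence_effect(1, 0), 1)
  expect_error(derive_abstinence_effect(0.3, 0.4), "invalid-parameter")
  expect_error(derive_abstinence_effect(1.2, 0.4), "invalid-parameter")
})

test_that("adherence gain is the non-adherence fraction difference", {
  expect_equal(derive_adherence_gain(c(19, 69), c(112, 1439)),
               19 / 69 - 112 / 1439)
  expect_equal(round(100 * derive_adherence_gain(c(19, 69), c(112, 1439)),
                     2), 19.75)
  expect_equal(derive_adherence_gain(c(0, 10), c(0, 10)), 0)
  expect_equal(derive_adherence_gain(c(69, 69), c(0, 1439)), 1)
  expect_error(derive_adherence_gain(c(1, 0), c(0, 10)),
               "invalid-parameter")
})

test_that("CPI inflation matches the published price-level ratios", {
  expect_equal(inflate_cpi(88.4, 2009, 2013, base_ctx),
               88.4 * 140.103 / 100)
  expect_equal(round(inflate_cpi(88.4, 2009, 2013, base_ctx)), 124)
  expect_equal(inflate_cpi(57.3, 2011, 2011, base_ctx), 57.3)
  expect_equal(inflate_cpi(100, 2009, 2010, base_ctx), 106.265)
  expect_error(inflate_cpi(10, 2009, 2012, base_ctx), "missing-cpi-year")
})

test_that("CPI inflation is multiplicative-transitive across years", {
  via_2010 <- inflate_cpi(inflate_cpi(250, 2009, 2010, base_ctx),
                          2010, 2013, base_ctx)
  expect_equal(via_2010, inflate_cpi(250, 2009, 2013, base_ctx))
})

test_that("currency conversion uses the fixed exchange rate both ways", {
  expect_equal(round(kes_to_usd(752555, base_ctx), 2), 8902.82)
  expect_equal(kes_to_usd(0, base_ctx), 0)
  expect_equal(kes_to_usd(84.53, base_ctx), 1)
  for (x in c(0.37, 12, 4369168))
    expect_equal(kes_to_usd(usd_to_kes(x, base_ctx), base_ctx), x)
})

test_that("annual HIV treatment cost sums inflated non-drug and drug parts", {
  expect_equal(annual_hiv_treatment_cost(base_params_fixture, base_ctx),
               88.4 * 1.40103 + 145.47)
  no_drug <- model_parameters(arv_drug_cost = 0)
  expect_equal(annual_hiv_treatment_cost(no_drug, base_ctx),
               88.4 * 1.40103)
  hi_fixed <- model_parameters(nondrug_costs_2009 = c(
    lab_tests = 32, clinic_visits = 24, support_services = 0.4,
    fixed_costs = 46.6))
  expect_equal(annual_hiv_treatment_cost(hi_fixed, base_ctx),
               103 * 1.40103 + 145.47)
})

test_that("derived composites reproduce the stored base values", {
  p <- base_params_fixture
  expect_identical(p$delta_abstinence,
                   derive_abstinence_effect(p$p_abst_cbt, p$p_abst_uc))
  expect_identical(p$adherence_gain,
                   derive_adherence_gain(p$adherence_counts$hazardous,
                                         p$adherence_counts$nondrinker))
  expect_equal(p$delta_abstinence, 0.31)
  expect_equal(round(100 * p$adherence_gain, 2), 19.75)
})

test_that("parameter validation names the offending field", {
  expect_error(model_parameters(p_abst_cbt = 1.2), "p_abst_cbt")
  expect_error(model_parameters(alcohol_attrib_frac = -0.1),
               "alcohol_attrib_frac")
  expect_error(model_parameters(house_wage = -1), "house_wage")
  expect_error(economic_context(exchange_rate = 0), "invalid-parameter")
  expect_error(economic_context(cpi = c("2009" = 100), reference_year =
                                  2013), "missing-cpi-year")
  expect_error(parameter_spec("x", 5, 6, 7), "invalid-parameter")
  expect_error(parameter_spec("x", 5, 4, 7, distribution = "normal_ci"),
               "invalid-parameter")
})
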