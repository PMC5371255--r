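# Shared fixtures: the bundled base case, loaded once per test run.
base_ctx <- economic_context()
base_params_fixture <- model_parameters()
base_sched <- rollout_schedule()
base_training <- training_cost_ledger(base_ctx)
base_site <- site_cost_ledger(base_ctx)
base_specs <- base_parameter_specs()

base_inputs <- function() {
  model_inputs(base_params_fixture, base_ctx, base_training, base_site,
               base_sched)
}

# A small hand-checkable ledger
toy_items <- data.frame(
  label = c("a", "b", "c"),
  category = c("X", "X", "Y"),
  unit = "piece",
  n_units = c(2, 1, 10),
  unit_cost_kes = c(500, 845.3, 10),
  stringsAsFactors = FALSE)
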