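#' Bundle of deterministic model inputs
#'
#' Groups everything the deterministic engine needs so sensitivity analyses
#' can perturb one input at a time and re-run [run_cba()].
#'
#' @param params A [model_parameters()].
#' @param ctx An [economic_context()].
#' @param training,per_site [cost_ledger()]s.
#' @param sched A [rollout_schedule()].
#' @param effect_length,discount_rate Engine settings; default from
#'   `params` / `ctx`.
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(params = model_parameters(),
                         ctx = economic_context(),
                         training = training_cost_ledger(ctx),
                         per_site = site_cost_ledger(ctx),
                         sched = rollout_schedule(),
                         effect_length = params$effect_length,
                         discount_rate = ctx$discount_rate) {
  structure(list(params = params, ctx = ctx, training = training,
                 per_site = per_site, sched = sched,
                 effect_length = effect_length,
                 discount_rate = discount_rate),
            class = "model_inputs")
}

#' Run the CBA for a bundle of model inputs
#' @param inputs A [model_inputs()].
#' @return A `cba_result` (see [run_cba()]).
#' @export
evaluate_model <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  run_cba(inputs$params, inputs$ctx, inputs$training, inputs$per_site,
          inputs$sched, inputs$effect_length, inputs$discount_rate)
}

# Map a sensitivity-parameter name to a perturbed copy of the inputs.
# Composite parameters (the abstinence-rate difference, the adherence gain)
# are overridden directly, not re-derived from their components, because the
# sensitivity ranges are stated on the composites.
apply_override <- function(inputs, name, value) {
  stopifnot(inherits(inputs, "model_inputs"))
  p <- inputs$params
  direct <- c("delta_abstinence", "alcohol_attrib_frac", "adherence_gain",
              "arv_drug_cost", "monthly_min_wage", "lfp_rise",
              "hp_hours_firewood", "hp_hours_water", "house_wage",
              "female_fraction", "annualization_weeks")
  nondrug <- c(lab_tests_2009 = "lab_tests",
               clinic_visits_2009 = "clinic_visits",
               support_services_2009 = "support_services",
               fixed_costs_2009 = "fixed_costs")
  if (name %in% direct) {
    p[[name]] <- value
    validate_model_parameters(p)
    inputs$params <- p
  } else if (name %in% names(nondrug)) {
    p$nondrug_costs_2009[[nondrug[[name]]]] <- value
    validate_model_parameters(p)
    inputs$params <- p
  } else if (name == "effect_length") {
    if (value < 1)
      stop("invalid-parameter: effect_length must be >= 1", call. = FALSE)
    inputs$effect_length <- value
  } else if (name == "discount_rate") {
    if (value < 0)
      stop("invalid-parameter: discount_rate must be >= 0", call. = FALSE)
    inputs$discount_rate <- value
  } else if (name == "transport_kes_per_visit") {
    base_rate <- inputs$sched$transport_kes_per_visit
    if (base_rate <= 0)
      stop("invalid-parameter: base transport rate must be > 0 to scale",
           call. = FALSE)
    inputs$per_site <- scale_ledger(inputs$per_site, value / base_rate,
                                    inputs$ctx,
                                    categories = "Participant Payments")
    inputs$sched$transport_kes_per_visit <- value
  } else if (name == "cost_multiplier") {
    inputs$training <- scale_ledger(inputs$training, value, inputs$ctx)
    inputs$per_site <- scale_ledger(inputs$per_site, value, inputs$ctx)
  } else {
    stop("unknown-parameter: '", name,
         "' does not resolve to a model input", call. = FALSE)
  }
  inputs
}

#' Default one-way sensitivity ranges
#'
#' One row per varied input: every uncertain model input from the bundled
#' parameter-specification fixture, plus the treatment-effect length (1-10
#' years), the discount rate (0-6%), the participant transport
#' reimbursement (0-500 KES/visit), and a program cost-per-participant
#' multiplier (0.5-2).
#'
#' @return data.frame with columns `parameter`, `low`, `high`.
#' @export
default_tornado_ranges <- function() {
  specs <- base_parameter_specs()
  tab <- data.frame(
    parameter = vapply(specs, `[[`, "", "name"),
    low = vapply(specs, `[[`, 0, "low"),
    high = vapply(specs, `[[`, 0, "high"),
    stringsAsFactors = FALSE)
  extras <- data.frame(
    parameter = c("effect_length", "discount_rate",
                  "transport_kes_per_visit", "cost_multiplier"),
    low = c(1, 0, 0, 0.5),
    high = c(10, 0.06, 500, 2),
    stringsAsFactors = FALSE)
  rbind(tab, extras)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full deterministic model with one input at a time set to
#' each bound of its range, all other inputs held at base, and ranks inputs
#' by the spread they induce in the benefit-to-cost ratio.
#'
#' @param inputs A [model_inputs()] bundle at base values.
#' @param vary data.frame with columns `parameter`, `low`, `high` (default
#'   [default_tornado_ranges()]).
#' @return data.frame of class `tornado_result` with columns `parameter`,
#'   `low_value`, `high_value`, `bcr_at_low`, `bcr_at_high`, `spread`,
#'   sorted by decreasing spread (ties broken by parameter name). The base
#'   BCR is attached as attribute `base_bcr`.
#' @export
#' @examples
#' tor <- tornado(model_inputs(),
#'                data.frame(parameter = "fixed_costs_2009",
#'                           low = 22.4, high = 46.6))
#' round(c(tor$bcr_at_low, tor$bcr_at_high), 2)  # ~1.11, ~1.17
tornado <- function(inputs = model_inputs(),
                    vary = default_tornado_ranges()) {
  stopifnot(is.data.frame(vary),
            all(c("parameter", "low", "high") %in% names(vary)))
  base_bcr <- evaluate_model(inputs)$bcr
  rows <- lapply(seq_len(nrow(vary)), function(i) {
    nm <- vary$parameter[i]
    b_lo <- evaluate_model(apply_override(inputs, nm, vary$low[i]))$bcr
    b_hi <- evaluate_model(apply_override(inputs, nm, vary$high[i]))$bcr
    data.frame(parameter = nm, low_value = vary$low[i],
               high_value = vary$high[i], bcr_at_low = b_lo,
               bcr_at_high = b_hi, spread = abs(b_hi - b_lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_bcr") <- base_bcr
  class(out) <- c("tornado_result", class(out))
  out
}
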