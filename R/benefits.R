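#' Benefit 1: annual per-patient savings from averted HIV incidence
#'
#' Product of the abstinence-rate difference (parameter 1.1), the fraction
#' of HIV incidence attributable to alcohol use (parameter 1.2), and the
#' annual per-patient HIV treatment cost (parameter 1.3).
#'
#' @param params A [model_parameters()].
#' @param ctx An [economic_context()].
#' @return 2013 USD per person-year.
#' @export
#' @examples
#' benefit1_per_person_year(model_parameters(), economic_context())  # ~10.85
benefit1_per_person_year <- function(params, ctx) {
  params$delta_abstinence * params$alcohol_attrib_frac *
    annual_hiv_treatment_cost(params, ctx)
}

#' Benefit 2: annual per-patient productivity gains
#'
#' Product of the abstinence-rate difference and the adherence gain
#' (parameter 2.2) with the annualized monetary value of the
#' adherence-mediated productivity hours (parameters 2.3/2.4): the
#' labor-force participation (LFP) gain, valued as a proportional rise in
#' annual minimum-wage income and counted for both sexes, plus the
#' household-productivity (HP) hour gains, valued at the house-worker wage
#' over `annualization_weeks` and counted only for the female fraction of
#' the cohort.
#'
#' @param params A [model_parameters()].
#' @return 2013 USD per person-year.
#' @export
#' @examples
#' benefit2_per_person_year(model_parameters())  # ~14.49
benefit2_per_person_year <- function(params) {
  v <- benefit2_components(params)
  v$lfp + v$hp
}

# LFP and HP components of benefit 2, before and after the female-fraction
# weighting, shared by the closed form and the reporting layer.
benefit2_components <- function(params) {
  lfp_value <- params$lfp_rise * params$monthly_min_wage *
    params$months_per_year
  hp_value <- (params$hp_hours_firewood + params$hp_hours_water) *
    params$house_wage * params$annualization_weeks
  scale <- params$delta_abstinence * params$adherence_gain
  list(lfp = scale * lfp_value,
       hp = scale * params$female_fraction * hp_value,
       lfp_annual_value = lfp_value, hp_annual_value = hp_value)
}

#' Per-person-year benefit breakdown
#'
#' @param params A [model_parameters()].
#' @param ctx An [economic_context()].
#' @return List with `b1_hiv`, `b2_lfp`, `b2_hp`, `total` (USD/person-year).
#' @export
per_person_year_benefit <- function(params, ctx) {
  b1 <- benefit1_per_person_year(params, ctx)
  v <- benefit2_components(params)
  out <- list(b1_hiv = b1, b2_lfp = v$lfp, b2_hp = v$hp,
              total = b1 + v$lfp + v$hp)
  class(out) <- "per_person_year_benefit"
  out
}

#' Nominal benefit stream by program year
#'
#' Each enrollment-year cohort accrues the per-person-year benefit for
#' `effect_length` consecutive years starting in its enrollment year, so
#' the stream extends `effect_length - 1` years beyond the last cost year.
#'
#' @param params A [model_parameters()].
#' @param ctx An [economic_context()].
#' @param sched A [rollout_schedule()].
#' @param effect_length Years the treatment effect lasts (default taken
#'   from `params`).
#' @return A [cash_flow()] in nominal USD, length
#'   `n_cost_years + effect_length - 1`.
#' @export
benefit_stream <- function(params, ctx, sched,
                           effect_length = params$effect_length) {
  stopifnot(inherits(sched, "rollout_schedule"), effect_length >= 1)
  effect_length <- as.integer(effect_length)
  pp <- per_person_year_benefit(params, ctx)$total
  sizes <- cohort_sizes(sched)
  horizon <- sched$n_cost_years + effect_length - 1L
  amounts <- numeric(horizon)
  for (c_year in seq_along(sizes)) {
    yrs <- c_year:(c_year + effect_length - 1L)
    amounts[yrs] <- amounts[yrs] + sizes[c_year] * pp
  }
  cash_flow(amounts)
}

#' @export
print.per_person_year_benefit <- function(x, ...) {
  cat("Per-person-year benefits (2013 USD)\n")
  cat(sprintf("  averted HIV treatment (benefit 1): %6.2f\n", x$b1_hiv))
  cat(sprintf("  labor-force productivity:          %6.2f\n", x$b2_lfp))
  cat(sprintf("  household productivity (females):  %6.2f\n", x$b2_hp))
  cat(sprintf("  total:                             %6.2f\n", x$total))
  invisible(x)
}
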