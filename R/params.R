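#' Economic context: discounting, currency, and price level
#'
#' Bundles the quantities needed to express all monetary flows in constant
#' 2013 US dollars: the annual discount rate, the KES-per-USD exchange rate,
#' and the Kenyan consumer price index (CPI) by calendar year.
#'
#' @param discount_rate Annual discount rate as a fraction (default 0.03).
#' @param exchange_rate Kenyan shillings per US dollar (default 84.53).
#' @param cpi Named numeric vector of CPI values, names = calendar years.
#' @param reference_year Calendar year for constant-dollar reporting.
#' @return An object of class `economic_context`.
#' @export
#' @examples
#' ctx <- economic_context()
#' kes_to_usd(752555, ctx)
economic_context <- function(discount_rate = 0.03,
                             exchange_rate = 84.53,
                             cpi = c("2009" = 100, "2010" = 106.265,
                                     "2011" = 121.17, "2013" = 140.103),
                             reference_year = 2013) {
  if (!is.numeric(discount_rate) || length(discount_rate) != 1L ||
      discount_rate < 0)
    stop("invalid-parameter: discount_rate must be a single value >= 0",
         call. = FALSE)
  if (!is.numeric(exchange_rate) || length(exchange_rate) != 1L ||
      exchange_rate <= 0)
    stop("invalid-parameter: exchange_rate must be > 0", call. = FALSE)
  if (is.null(names(cpi)) || any(!is.finite(cpi)) || any(cpi <= 0))
    stop("invalid-parameter: cpi must be a named vector of positive values",
         call. = FALSE)
  if (!as.character(reference_year) %in% names(cpi))
    stop("missing-cpi-year: reference_year ", reference_year,
         " absent from cpi table", call. = FALSE)
  structure(list(discount_rate = discount_rate,
                 exchange_rate = exchange_rate,
                 cpi = cpi,
                 reference_year = as.integer(reference_year)),
            class = "economic_context")
}

#' Specification of a single uncertain model input
#'
#' Records an input's base value, its sensitivity range, and the
#' distribution family used when the input is drawn in the probabilistic
#' sensitivity analysis.
#'
#' @param name Identifier used to address the input in sensitivity analyses.
#' @param base Base-case value.
#' @param low,high Bounds of the one-way sensitivity range (`low <= base <=
#'   high`).
#' @param units Free-text units.
#' @param distribution One of `"right_skewed_cost"` (lognormal, median at
#'   base, central 95% spanning `[low, high]`), `"normal_ci"` (normal with
#'   the reported standard error), `"uniform_range"`, or `"fixed"`.
#' @param se Standard error; required for `"normal_ci"`.
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, base, low = base, high = base,
                           units = "",
                           distribution = c("fixed", "right_skewed_cost",
                                            "normal_ci", "uniform_range"),
                           se = NULL) {
  distribution <- match.arg(distribution)
  if (!(low <= base && base <= high))
    stop("invalid-parameter: '", name, "' needs low <= base <= high",
         call. = FALSE)
  if (distribution == "normal_ci" && (is.null(se) || se <= 0))
    stop("invalid-parameter: '", name,
         "' uses normal_ci and needs se > 0", call. = FALSE)
  structure(list(name = name, base = base, low = low, high = high,
                 units = units, distribution = distribution,
                 se = if (is.null(se)) NA_real_ else se),
            class = "parameter_spec")
}

#' Abstinence-rate difference between CBT and usual care (parameter 1.1)
#'
#' The incremental probability that a treated patient reports alcohol
#' abstinence, computed as the CBT arm's 90-day abstinence rate minus the
#' usual-care rate.
#'
#' @param p_cbt Abstinence rate in the CBT arm (fraction).
#' @param p_uc Abstinence rate under usual care (fraction).
#' @return `p_cbt - p_uc`.
#' @export
#' @examples
#' derive_abstinence_effect(0.69, 0.38)  # 0.31
derive_abstinence_effect <- function(p_cbt, p_uc) {
  stopifnot(is.numeric(p_cbt), is.numeric(p_uc))
  if (p_cbt < 0 || p_cbt > 1 || p_uc < 0 || p_uc > 1)
    stop("invalid-parameter: abstinence rates must lie in [0, 1]",
         call. = FALSE)
  if (p_cbt < p_uc)
    stop("invalid-parameter: CBT abstinence rate below usual care; ",
         "negative effects are not supported by the base model",
         call. = FALSE)
  p_cbt - p_uc
}

#' Adherence gain from moving to abstinence (parameter 2.2)
#'
#' Difference between the non-adherence fraction among hazardous drinkers
#' and among non-drinkers: the increase in the probability of full ARV
#' adherence when a patient moves from non-abstinence to abstinence.
#'
#' @param hazardous Length-2 count pair `c(nonadherent, exposed)` among
#'   hazardous drinkers.
#' @param nondrinker Same pair among non-drinkers.
#' @return Fraction `hazardous[1]/hazardous[2] - nondrinker[1]/nondrinker[2]`.
#' @export
#' @examples
#' derive_adherence_gain(c(19, 69), c(112, 1439))  # 0.19753
derive_adherence_gain <- function(hazardous, nondrinker) {
  chk <- function(p, lbl) {
    if (length(p) != 2L || anyNA(p) || p[2] <= 0 || p[1] < 0 || p[1] > p[2])
      stop("invalid-parameter: ", lbl,
           " must be (events, exposed) with 0 <= events <= exposed, ",
           "exposed > 0", call. = FALSE)
  }
  chk(hazardous, "hazardous"); chk(nondrinker, "nondrinker")
  hazardous[1] / hazardous[2] - nondrinker[1] / nondrinker[2]
}

#' Re-express an amount in another year's price level
#'
#' Multiplies by the ratio of CPI values, so 2009-denominated costs can be
#' stated in constant 2013 dollars.
#'
#' @param amount Monetary amount.
#' @param from_year,to_year Calendar years; both must be in `ctx$cpi`.
#' @param ctx An [economic_context()].
#' @return `amount * cpi[to_year] / cpi[from_year]`.
#' @export
#' @examples
#' inflate_cpi(88.4, 2009, 2013, economic_context())  # 123.85
inflate_cpi <- function(amount, from_year, to_year, ctx) {
  stopifnot(inherits(ctx, "economic_context"))
  fy <- as.character(from_year); ty <- as.character(to_year)
  missing_y <- setdiff(c(fy, ty), names(ctx$cpi))
  if (length(missing_y))
    stop("missing-cpi-year: no CPI value for ",
         paste(missing_y, collapse = ", "), call. = FALSE)
  amount * ctx$cpi[[ty]] / ctx$cpi[[fy]]
}

#' Convert Kenyan shillings to US dollars
#' @param amount_kes Amount in KES (>= 0).
#' @param ctx An [economic_context()].
#' @return Amount in USD.
#' @export
kes_to_usd <- function(amount_kes, ctx) {
  stopifnot(inherits(ctx, "economic_context"), all(amount_kes >= 0))
  amount_kes / ctx$exchange_rate
}

#' Convert US dollars to Kenyan shillings
#' @param amount_usd Amount in USD (>= 0).
#' @param ctx An [economic_context()].
#' @return Amount in KES.
#' @export
usd_to_kes <- function(amount_usd, ctx) {
  stopifnot(inherits(ctx, "economic_context"), all(amount_usd >= 0))
  amount_usd * ctx$exchange_rate
}

#' Full set of model inputs at their base-case values
#'
#' Collects every model input: trial abstinence rates and their difference,
#' the alcohol-attributable fraction of HIV incidence, the components of the
#' annual per-patient HIV treatment cost, the adherence-gain source counts,
#' the labor-force and household productivity inputs, and structural
#' constants. Composite parameters (`delta_abstinence`, `adherence_gain`)
#' are derived from their printed components unless overridden, which the
#' sensitivity analyses use to vary the composites directly.
#'
#' @param p_abst_cbt,p_abst_uc 90-day abstinence rates (CBT arm / usual care).
#' @param delta_abstinence Optional override of the derived difference.
#' @param alcohol_attrib_frac Fraction of HIV incidence attributable to
#'   alcohol use.
#' @param nondrug_costs_2009 Named vector (`lab_tests`, `clinic_visits`,
#'   `support_services`, `fixed_costs`) of per-patient-year costs, 2009 USD.
#' @param arv_drug_cost Annual first-line ARV regimen cost, 2013 USD.
#' @param adherence_counts List with count pairs `hazardous` and
#'   `nondrinker` (non-adherent, exposed).
#' @param adherence_gain Optional override of the derived adherence gain.
#' @param lfp_rise Rise in weekly hours worked after ARV treatment, as a
#'   fraction of baseline hours.
#' @param lfp_se_hours,lfp_baseline_hours Standard error (hours/week) and
#'   baseline weekly hours behind `lfp_rise`.
#' @param monthly_min_wage Average monthly minimum wage, USD.
#' @param hp_hours_firewood,hp_hours_water Weekly household-productivity
#'   hour gains (firewood / water collection), females only.
#' @param hp_se_firewood,hp_se_water Their standard errors.
#' @param house_wage Hourly minimum wage for a house worker, USD.
#' @param female_fraction Fraction of the cohort that is female.
#' @param effect_length Years the treatment effect persists (base 2).
#' @param annualization_weeks Weeks/year used to annualize weekly hours.
#' @param months_per_year Months per year (12).
#' @return An object of class `model_parameters`.
#' @export
#' @examples
#' p <- model_parameters()
#' p$delta_abstinence  # 0.31
model_parameters <- function(p_abst_cbt = 0.69,
                             p_abst_uc = 0.38,
                             delta_abstinence = NULL,
                             alcohol_attrib_frac = 0.13,
                             nondrug_costs_2009 = c(lab_tests = 32,
                                                    clinic_visits = 24,
                                                    support_services = 0.4,
                                                    fixed_costs = 32),
                             arv_drug_cost = 145.47,
                             adherence_counts = list(
                               hazardous = c(19, 69),
                               nondrinker = c(112, 1439)),
                             adherence_gain = NULL,
                             lfp_rise = 0.19,
                             lfp_se_hours = 1.88,
                             lfp_baseline_hours = 24.3,
                             monthly_min_wage = 76.93,
                             hp_hours_firewood = 1.056,
                             hp_hours_water = 1.945,
                             hp_se_firewood = 0.461,
                             hp_se_water = 0.556,
                             house_wage = 0.85,
                             female_fraction = 0.5,
                             effect_length = 2,
                             annualization_weeks = 48,
                             months_per_year = 12) {
  if (p_abst_cbt < 0 || p_abst_cbt > 1)
    stop("validation-error: field 'p_abst_cbt' must be a fraction in [0, 1]",
         call. = FALSE)
  if (p_abst_uc < 0 || p_abst_uc > 1)
    stop("validation-error: field 'p_abst_uc' must be a fraction in [0, 1]",
         call. = FALSE)
  if (is.null(delta_abstinence))
    delta_abstinence <- derive_abstinence_effect(p_abst_cbt, p_abst_uc)
  if (is.null(adherence_gain))
    adherence_gain <- derive_adherence_gain(adherence_counts$hazardous,
                                            adherence_counts$nondrinker)
  p <- list(p_abst_cbt = p_abst_cbt, p_abst_uc = p_abst_uc,
            delta_abstinence = delta_abstinence,
            alcohol_attrib_frac = alcohol_attrib_frac,
            nondrug_costs_2009 = nondrug_costs_2009,
            arv_drug_cost = arv_drug_cost,
            adherence_counts = adherence_counts,
            adherence_gain = adherence_gain,
            lfp_rise = lfp_rise, lfp_se_hours = lfp_se_hours,
            lfp_baseline_hours = lfp_baseline_hours,
            monthly_min_wage = monthly_min_wage,
            hp_hours_firewood = hp_hours_firewood,
            hp_hours_water = hp_hours_water,
            hp_se_firewood = hp_se_firewood, hp_se_water = hp_se_water,
            house_wage = house_wage, female_fraction = female_fraction,
            effect_length = effect_length,
            annualization_weeks = annualization_weeks,
            months_per_year = months_per_year)
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

validate_model_parameters <- function(p) {
  frac <- c("p_abst_cbt", "p_abst_uc", "delta_abstinence",
            "alcohol_attrib_frac", "adherence_gain", "female_fraction")
  for (f in frac)
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1)
      stop("validation-error: field '", f, "' must be a fraction in [0, 1]",
           call. = FALSE)
  nonneg <- c("arv_drug_cost", "lfp_rise", "monthly_min_wage",
              "hp_hours_firewood", "hp_hours_water", "house_wage",
              "annualization_weeks", "lfp_baseline_hours")
  for (f in nonneg)
    if (!is.numeric(p[[f]]) || any(p[[f]] < 0))
      stop("validation-error: field '", f, "' must be >= 0", call. = FALSE)
  if (any(p$nondrug_costs_2009 < 0))
    stop("validation-error: field 'nondrug_costs_2009' must be >= 0",
         call. = FALSE)
  need <- c("lab_tests", "clinic_visits", "support_services", "fixed_costs")
  if (!all(need %in% names(p$nondrug_costs_2009)))
    stop("validation-error: field 'nondrug_costs_2009' must name ",
         paste(need, collapse = ", "), call. = FALSE)
  if (p$effect_length < 1)
    stop("validation-error: field 'effect_length' must be >= 1",
         call. = FALSE)
  invisible(p)
}

#' Annual per-patient cost of treating HIV (parameter 1.3)
#'
#' Sum of the CPI-inflated 2009 non-drug components (lab tests, clinic
#' visits, support services, hospital fixed costs) and the 2013 annual cost
#' of a first-line tenofovir/3TC/EFV regimen, in 2013 USD per patient-year.
#'
#' @param params A [model_parameters()] object.
#' @param ctx An [economic_context()].
#' @return 2013 USD per patient-year.
#' @export
#' @examples
#' annual_hiv_treatment_cost(model_parameters(), economic_context())  # 269.3
annual_hiv_treatment_cost <- function(params, ctx) {
  stopifnot(inherits(params, "model_parameters"))
  nondrug_2013 <- inflate_cpi(sum(params$nondrug_costs_2009), 2009,
                              ctx$reference_year, ctx)
  nondrug_2013 + params$arv_drug_cost
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (base case)\n")
  cat(sprintf("  abstinence effect (CBT - usual care): %.2f\n",
              x$delta_abstinence))
  cat(sprintf("  alcohol-attributable HIV incidence:   %.3f\n",
              x$alcohol_attrib_frac))
  cat(sprintf("  adherence gain from abstinence:       %.4f\n",
              x$adherence_gain))
  cat(sprintf("  treatment effect length:              %d year(s)\n",
              as.integer(x$effect_length)))
  invisible(x)
}
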