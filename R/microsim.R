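#' Generate a synthetic participant roster
#'
#' Simulates individual participants under the model's assumed
#' data-generating process so cohort-level closed forms can be checked by
#' person-level accounting. Each participant gets a sex (Bernoulli at the
#' female fraction), an enrollment cohort year from the rollout schedule,
#' an indicator of CBT-attributable sustained abstinence (Bernoulli at the
#' abstinence-rate difference), an adherence-gain indicator (Bernoulli at
#' the adherence gain, drawn only for the abstinent), a labor-force hour
#' gain drawn normal on the fraction-of-baseline scale (mean `lfp_rise`,
#' SE `lfp_se_hours / lfp_baseline_hours`), and, for females, household
#' hour gains drawn from the two normal components (firewood, water).
#' Negative hour draws are clamped at zero; the clamp count is attached as
#' attribute `clamp_count`.
#'
#' @param params A [model_parameters()].
#' @param sched A [rollout_schedule()].
#' @param seed Integer seed; the roster is reproducible from it.
#' @return data.frame with columns `id`, `sex`, `cohort_year`, `abstinent`,
#'   `adherent_gain`, `lfp_gain_frac`, `hp_gain_hours`.
#' @export
#' @examples
#' roster <- generate_cohort(model_parameters(), rollout_schedule(), 1)
#' nrow(roster)  # 13440
generate_cohort <- function(params = model_parameters(),
                            sched = rollout_schedule(), seed = 1L) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(sched, "rollout_schedule"))
  set.seed(seed)
  sizes <- cohort_sizes(sched)
  n <- sum(sizes)
  cohort_year <- rep(seq_along(sizes), sizes)
  female <- stats::rbinom(n, 1L, params$female_fraction)
  abstinent <- stats::rbinom(n, 1L, params$delta_abstinence)
  adherent <- abstinent * stats::rbinom(n, 1L, params$adherence_gain)
  lfp <- stats::rnorm(n, params$lfp_rise,
                      params$lfp_se_hours / params$lfp_baseline_hours)
  fw <- stats::rnorm(n, params$hp_hours_firewood, params$hp_se_firewood)
  wt <- stats::rnorm(n, params$hp_hours_water, params$hp_se_water)
  clamp_count <- sum(lfp < 0) + sum(female == 1L & (fw < 0 | wt < 0))
  lfp <- pmax(lfp, 0)
  hp <- ifelse(female == 1L, pmax(fw, 0) + pmax(wt, 0), 0)
  out <- data.frame(id = seq_len(n),
                    sex = ifelse(female == 1L, "female", "male"),
                    cohort_year = cohort_year,
                    abstinent = abstinent,
                    adherent_gain = adherent,
                    lfp_gain_frac = lfp,
                    hp_gain_hours = hp,
                    stringsAsFactors = FALSE)
  attr(out, "clamp_count") <- clamp_count
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Total discounted benefit from person-level accounting
#'
#' Brute-force oracle for the cohort closed forms: each participant's
#' realized annual benefit (averted HIV treatment costs if abstinent;
#' adherence-mediated wage and household-production gains if the adherence
#' gain is realized) is accrued over the effect years from their cohort's
#' enrollment year, discounted end-of-year, and summed. Its expectation
#' over rosters equals the closed-form discounted total of
#' [benefit_stream()].
#'
#' @param cohort A roster from [generate_cohort()].
#' @param params A [model_parameters()].
#' @param ctx An [economic_context()].
#' @param effect_length Years each participant accrues benefits.
#' @param discount_rate Annual rate (default from `ctx`).
#' @return Total discounted USD.
#' @export
microsim_benefit_total <- function(cohort, params, ctx,
                                   effect_length = params$effect_length,
                                   discount_rate = ctx$discount_rate) {
  stopifnot(is.data.frame(cohort), effect_length >= 1)
  treat_cost <- annual_hiv_treatment_cost(params, ctx)
  b1 <- cohort$abstinent * params$alcohol_attrib_frac * treat_cost
  lfp_value <- cohort$lfp_gain_frac * params$monthly_min_wage *
    params$months_per_year
  hp_value <- cohort$hp_gain_hours * params$house_wage *
    params$annualization_weeks
  annual <- b1 + cohort$adherent_gain * (lfp_value + hp_value)
  # annuity of effect_length end-of-year payments starting in cohort year
  years <- sort(unique(cohort$cohort_year))
  ann_by_year <- vapply(years, function(c_year) {
    t <- c_year:(c_year + effect_length - 1L)
    sum(1 / (1 + discount_rate)^(t - 1))
  }, 0)
  sum(annual * ann_by_year[match(cohort$cohort_year, years)])
}
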