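#' Build a random sampler for an uncertain input
#'
#' Maps a [parameter_spec()] to a draw function following the model's
#' distribution rules: costs get a right-skewed lognormal with median at
#' the base value and the central 95% of mass spanning `[low, high]`
#' (`sdlog = log(high/low) / (2 * 1.96)`); inputs whose ranges are
#' confidence intervals get a normal with the reported standard error;
#' other ranges are uniform; `fixed` inputs are degenerate at base.
#'
#' @param spec A [parameter_spec()].
#' @return A function `f(n)` returning `n` draws.
#' @export
#' @examples
#' set.seed(1)
#' f <- assign_distribution(parameter_spec("u", 0.09, 0.018, 0.165,
#'                                         distribution = "uniform_range"))
#' mean(f(1e4))  # ~ (0.018 + 0.165) / 2
assign_distribution <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  switch(spec$distribution,
    fixed = function(n) rep(spec$base, n),
    uniform_range = function(n) stats::runif(n, spec$low, spec$high),
    normal_ci = function(n) stats::rnorm(n, spec$base, spec$se),
    right_skewed_cost = {
      if (spec$low <= 0)
        stop("unsupported-distribution: right_skewed_cost needs low > 0",
             call. = FALSE)
      sdlog <- log(spec$high / spec$low) / (2 * stats::qnorm(0.975))
      function(n) stats::rlnorm(n, log(spec$base), sdlog)
    },
    stop("unsupported-distribution: ", spec$distribution, call. = FALSE))
}

# Inputs sampled on the fraction scale are clamped to [0, 1]; everything
# else (costs, wages, hours) to >= 0. The model is silent on out-of-range
# draws, so clamps are counted and reported on the result.
psa_fraction_inputs <- c("delta_abstinence", "alcohol_attrib_frac",
                         "adherence_gain", "lfp_rise", "female_fraction")

#' Draw all uncertain inputs simultaneously
#'
#' @param specs List of [parameter_spec()]s (default the bundled Table of
#'   base specifications, [base_parameter_specs()]).
#' @param n Number of joint draws.
#' @return data.frame, one column per input, with attribute `clamp_counts`
#'   (named integer vector of out-of-range draws clamped per input).
#' @export
draw_parameters <- function(specs = base_parameter_specs(), n) {
  draws <- list()
  clamps <- integer(length(specs))
  names(clamps) <- vapply(specs, `[[`, "", "name")
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    x <- assign_distribution(s)(n)
    hi <- if (s$name %in% psa_fraction_inputs) 1 else Inf
    n_bad <- sum(x < 0 | x > hi)
    x <- pmin(pmax(x, 0), hi)
    clamps[[s$name]] <- n_bad
    draws[[s$name]] <- x
  }
  out <- as.data.frame(draws)
  attr(out, "clamp_counts") <- clamps
  out
}

# Per-person-year benefit for a data.frame of joint draws; columns missing
# from `draws` stay at their base value. Vectorized over rows.
per_person_benefit_draws <- function(draws, params, ctx) {
  g <- function(nm, base) if (nm %in% names(draws)) draws[[nm]] else base
  nd <- params$nondrug_costs_2009
  nondrug <- g("lab_tests_2009", nd[["lab_tests"]]) +
    g("clinic_visits_2009", nd[["clinic_visits"]]) +
    g("support_services_2009", nd[["support_services"]]) +
    g("fixed_costs_2009", nd[["fixed_costs"]])
  treat_cost <- inflate_cpi(nondrug, 2009, ctx$reference_year, ctx) +
    g("arv_drug_cost", params$arv_drug_cost)
  delta <- g("delta_abstinence", params$delta_abstinence)
  b1 <- delta * g("alcohol_attrib_frac", params$alcohol_attrib_frac) *
    treat_cost
  lfp_value <- g("lfp_rise", params$lfp_rise) *
    g("monthly_min_wage", params$monthly_min_wage) * params$months_per_year
  hp_value <- (g("hp_hours_firewood", params$hp_hours_firewood) +
                 g("hp_hours_water", params$hp_hours_water)) *
    g("house_wage", params$house_wage) * params$annualization_weeks
  b2 <- delta * g("adherence_gain", params$adherence_gain) *
    (lfp_value + params$female_fraction * hp_value)
  b1 + b2
}

# Discounted person-year weight: sum over cohorts of cohort size times the
# end-of-year discount annuity over the effect years. Multiplying by the
# per-person-year benefit gives the total discounted benefit.
discounted_personyear_weight <- function(sched, effect_length, rate) {
  sizes <- cohort_sizes(sched)
  w <- 0
  for (c_year in seq_along(sizes)) {
    t <- c_year:(c_year + effect_length - 1L)
    w <- w + sizes[c_year] * sum(1 / (1 + rate)^(t - 1))
  }
  w
}

#' Configuration for the probabilistic sensitivity analysis
#'
#' @param n_reps Replications per effect-length scenario (default 10,000).
#' @param effect_lengths Treatment-effect durations to simulate, in years.
#' @param seed Integer seed; recorded in all outputs.
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_reps = 10000L,
                       effect_lengths = c(1L, 2L, 3L, 4L, 5L, 10L),
                       seed = 1L) {
  if (n_reps < 1L) stop("validation-error: n_reps must be >= 1",
                        call. = FALSE)
  if (any(effect_lengths < 1L))
    stop("validation-error: effect lengths must be >= 1", call. = FALSE)
  structure(list(n_reps = as.integer(n_reps),
                 effect_lengths = as.integer(effect_lengths),
                 seed = as.integer(seed)),
            class = "psa_config")
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' For each treatment-effect-length scenario, jointly draws every uncertain
#' input `n_reps` times from its assigned distribution, evaluates the full
#' deterministic cost-benefit model for each draw (program costs held at
#' their ledger values; the time horizon extends with the effect length),
#' and summarizes the distribution of benefit-to-cost ratios.
#'
#' @param cfg A [psa_config()].
#' @param inputs A [model_inputs()] bundle at base values.
#' @param specs List of [parameter_spec()]s to sample (default
#'   [base_parameter_specs()]).
#' @param keep_draws If `TRUE`, the per-replicate BCR vectors are attached
#'   as attribute `draws` (a named list by effect length).
#' @return data.frame of class `psa_result`: one row per effect length with
#'   `mean_bcr`, percentile interval (`ci_low`, `ci_high`), a normal CI of
#'   the mean (`ci_mean_low`, `ci_mean_high`), `sd_bcr`, `n_reps`, `seed`.
#'   Attribute `clamp_counts` reports out-of-range draws clamped.
#' @export
#' @examples
#' run_psa(psa_config(n_reps = 200, effect_lengths = c(1, 2), seed = 7))
run_psa <- function(cfg = psa_config(), inputs = model_inputs(),
                    specs = base_parameter_specs(), keep_draws = FALSE) {
  stopifnot(inherits(cfg, "psa_config"), inherits(inputs, "model_inputs"))
  set.seed(cfg$seed)
  cost_total <- sum(discount(
    cost_stream(inputs$training, inputs$per_site, inputs$sched),
    inputs$discount_rate)$amounts)
  if (cost_total <= 0)
    stop("zero-cost: discounted program costs are zero; BCR undefined",
         call. = FALSE)
  rows <- vector("list", length(cfg$effect_lengths))
  all_draws <- list()
  clamp_total <- NULL
  for (i in seq_along(cfg$effect_lengths)) {
    L <- cfg$effect_lengths[i]
    d <- draw_parameters(specs, cfg$n_reps)
    cl <- attr(d, "clamp_counts")
    clamp_total <- if (is.null(clamp_total)) cl else clamp_total + cl
    pp <- per_person_benefit_draws(d, inputs$params, inputs$ctx)
    w <- discounted_personyear_weight(inputs$sched, L,
                                      inputs$discount_rate)
    bcr <- pp * w / cost_total
    if (any(!is.finite(bcr)))
      stop("replicate-error: non-finite BCR in effect-length ", L,
           " scenario", call. = FALSE)
    q <- stats::quantile(bcr, c(0.025, 0.975), names = FALSE)
    m <- mean(bcr)
    s <- if (cfg$n_reps > 1L) stats::sd(bcr) else 0
    half <- stats::qnorm(0.975) * s / sqrt(cfg$n_reps)
    rows[[i]] <- data.frame(effect_length = L, mean_bcr = m,
                            ci_low = q[1], ci_high = q[2],
                            ci_mean_low = m - half, ci_mean_high = m + half,
                            sd_bcr = s, n_reps = cfg$n_reps,
                            seed = cfg$seed)
    if (keep_draws) all_draws[[as.character(L)]] <- bcr
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "clamp_counts") <- clamp_total
  if (keep_draws) attr(out, "draws") <- all_draws
  class(out) <- c("psa_result", class(out))
  out
}
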