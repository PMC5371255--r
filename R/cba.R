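#' Year-indexed monetary stream
#'
#' @param amounts Numeric vector of USD amounts, one per program year.
#' @param start_year Index of the first year (default 1).
#' @return An object of class `cash_flow`.
#' @export
cash_flow <- function(amounts, start_year = 1L) {
  if (!is.numeric(amounts) || length(amounts) < 1L ||
      any(!is.finite(amounts)))
    stop("validation-error: cash flow amounts must be finite and non-empty",
         call. = FALSE)
  structure(list(start_year = as.integer(start_year),
                 amounts = as.numeric(amounts)),
            class = "cash_flow")
}

#' Discount a cash-flow series
#'
#' Flows are assumed to occur at the end of each year, so the year-1 amount
#' is undiscounted and the year-t amount is divided by `(1 + rate)^(t - 1)`.
#'
#' @param series A [cash_flow()].
#' @param rate Annual discount rate (fraction, >= 0).
#' @return A discounted [cash_flow()].
#' @export
#' @examples
#' discount(cash_flow(c(0, 103)), 0.03)$amounts  # c(0, 100)
discount <- function(series, rate) {
  stopifnot(inherits(series, "cash_flow"), rate >= 0)
  t <- seq_along(series$amounts) + series$start_year - 1L
  cash_flow(series$amounts / (1 + rate)^(t - 1), series$start_year)
}

#' Run the full deterministic cost-benefit analysis
#'
#' Composes the program cost stream (training plus per-site budgets over
#' the rollout years), the cohort benefit stream (averted HIV treatment
#' costs and productivity gains over the treatment-effect years),
#' end-of-year discounting, and the headline outputs: total discounted
#' costs and benefits, the benefit-to-cost ratio (BCR), net benefit, and
#' cost per participant. The time horizon is always
#' `n_cost_years + effect_length - 1` (six years in the base case).
#'
#' @param params A [model_parameters()].
#' @param ctx An [economic_context()].
#' @param training,per_site [cost_ledger()]s; default to the bundled
#'   fixtures.
#' @param sched A [rollout_schedule()].
#' @param effect_length Years the treatment effect lasts (default from
#'   `params`).
#' @param discount_rate Annual discount rate (default from `ctx`).
#' @return An object of class `cba_result`.
#' @export
#' @examples
#' res <- run_cba()
#' round(res$bcr, 2)  # 1.13
run_cba <- function(params = model_parameters(),
                    ctx = economic_context(),
                    training = training_cost_ledger(ctx),
                    per_site = site_cost_ledger(ctx),
                    sched = rollout_schedule(),
                    effect_length = params$effect_length,
                    discount_rate = ctx$discount_rate) {
  costs_nom <- cost_stream(training, per_site, sched)
  bens_nom <- benefit_stream(params, ctx, sched, effect_length)
  costs_disc <- discount(costs_nom, discount_rate)
  bens_disc <- discount(bens_nom, discount_rate)
  total_cost <- sum(costs_disc$amounts)
  total_ben <- sum(bens_disc$amounts)
  if (total_cost == 0)
    stop("zero-cost: discounted program costs are zero; BCR undefined",
         call. = FALSE)
  structure(list(total_cost_disc = total_cost,
                 total_benefit_disc = total_ben,
                 bcr = total_ben / total_cost,
                 net_benefit = total_ben - total_cost,
                 unit_cost = unit_cost(sum(costs_nom$amounts), sched),
                 unit_cost_disc = unit_cost(total_cost, sched),
                 per_year_costs = costs_nom,
                 per_year_benefits = bens_nom,
                 per_year_costs_disc = costs_disc,
                 per_year_benefits_disc = bens_disc,
                 effect_length = effect_length,
                 discount_rate = discount_rate),
            class = "cba_result")
}

#' @export
print.cba_result <- function(x, ...) {
  cat("Cost-benefit analysis (constant 2013 USD, end-of-year discounting)\n")
  cat(sprintf("  effect length:              %d year(s); horizon %d years\n",
              as.integer(x$effect_length),
              length(x$per_year_benefits$amounts)))
  cat(sprintf("  total discounted costs:     $%s\n",
              format(round(x$total_cost_disc / 1000) * 1000,
                     big.mark = ",", scientific = FALSE)))
  cat(sprintf("  total discounted benefits:  $%s\n",
              format(round(x$total_benefit_disc / 1000) * 1000,
                     big.mark = ",", scientific = FALSE)))
  cat(sprintf("  benefit-to-cost ratio:      %.2f\n", x$bcr))
  cat(sprintf("  net benefit:                $%s\n",
              format(round(x$net_benefit / 1000) * 1000,
                     big.mark = ",", scientific = FALSE)))
  cat(sprintf("  cost per participant:       $%.0f (undiscounted)\n",
              x$unit_cost))
  invisible(x)
}
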