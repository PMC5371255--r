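#' Build a cost ledger from line items
#'
#' Aggregates ingredient-based cost line items (units x unit cost, in KES)
#' into category subtotals and grand totals, with the USD total converted at
#' the context's exchange rate. Used for both the one-off training budget
#' and the recurring per-site annual budget.
#'
#' @param items data.frame with columns `label`, `category`, `unit`,
#'   `n_units`, `unit_cost_kes` and optionally `total_kes` (checked against
#'   `n_units * unit_cost_kes` to within 1 KES if supplied).
#' @param ctx An [economic_context()] supplying the exchange rate.
#' @return An object of class `cost_ledger` with elements `items`,
#'   `category_subtotals` (named KES vector), `grand_total_kes`,
#'   `grand_total_usd`.
#' @export
#' @examples
#' items <- data.frame(label = "chairs", category = "Furniture",
#'                     unit = "piece", n_units = 2, unit_cost_kes = 500)
#' cost_ledger(items, economic_context())$grand_total_kes  # 1000
cost_ledger <- function(items, ctx) {
  stopifnot(inherits(ctx, "economic_context"))
  need <- c("label", "category", "unit", "n_units", "unit_cost_kes")
  if (!is.data.frame(items) || nrow(items) == 0L ||
      !all(need %in% names(items)))
    stop("validation-error: ledger items need columns ",
         paste(need, collapse = ", "), " and at least one row",
         call. = FALSE)
  if (any(items$unit_cost_kes < 0) || any(items$n_units < 0))
    stop("validation-error: unit costs and unit counts must be >= 0",
         call. = FALSE)
  computed <- items$n_units * items$unit_cost_kes
  if ("total_kes" %in% names(items)) {
    bad <- which(abs(items$total_kes - computed) > 1)
    if (length(bad))
      stop("inconsistent-line-item: '", items$label[bad[1]],
           "' total_kes differs from n_units * unit_cost_kes by more ",
           "than 1 KES", call. = FALSE)
  }
  items$total_kes <- computed
  subtot <- tapply(items$total_kes, items$category, sum)
  subtot <- subtot[unique(items$category)]  # keep ledger order
  grand_kes <- sum(items$total_kes)
  structure(list(items = items,
                 category_subtotals = c(subtot),
                 grand_total_kes = grand_kes,
                 grand_total_usd = kes_to_usd(grand_kes, ctx)),
            class = "cost_ledger")
}

#' Read a cost ledger from a CSV file
#'
#' @param path CSV with columns `label`, `category`, `unit`, `n_units`,
#'   `unit_cost_kes`.
#' @param ctx An [economic_context()].
#' @return A [cost_ledger()].
#' @export
read_cost_ledger <- function(path, ctx) {
  if (!file.exists(path))
    stop("io-error: no such ledger file: ", path, call. = FALSE)
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  cost_ledger(items, ctx)
}

#' Bundled ledger fixtures: training and per-site scale-up budgets
#'
#' `training_cost_ledger()` transcribes the one-off training budget
#' (counselor and psychiatry consultants, per diems, materials, conference
#' center, start-up furniture and equipment; KES 4,369,168 / $51,688).
#' `site_cost_ledger()` transcribes the annual per-site budget (personnel,
#' supplies, participant transport payments; KES 752,555 / $8,903).
#'
#' @param ctx An [economic_context()].
#' @return A [cost_ledger()].
#' @export
training_cost_ledger <- function(ctx = economic_context()) {
  read_cost_ledger(system.file("extdata", "training_costs.csv",
                               package = "taskshiftCBA", mustWork = TRUE),
                   ctx)
}

#' @rdname training_cost_ledger
#' @export
site_cost_ledger <- function(ctx = economic_context()) {
  read_cost_ledger(system.file("extdata", "site_costs.csv",
                               package = "taskshiftCBA", mustWork = TRUE),
                   ctx)
}

#' Multiply every line item of a ledger by a factor
#'
#' Used by the sensitivity analyses to scale program costs (e.g. a
#' cost-per-participant multiplier) without touching the fixture files.
#'
#' @param ledger A [cost_ledger()].
#' @param factor Non-negative scale factor.
#' @param ctx An [economic_context()].
#' @param categories Optional character vector: only items whose `category`
#'   matches are scaled (e.g. `"Participant Payments"`).
#' @return A new [cost_ledger()].
#' @export
scale_ledger <- function(ledger, factor, ctx, categories = NULL) {
  stopifnot(inherits(ledger, "cost_ledger"), factor >= 0)
  items <- ledger$items
  sel <- if (is.null(categories)) rep(TRUE, nrow(items))
         else items$category %in% categories
  if (!any(sel))
    stop("unknown-parameter: no ledger items in categories ",
         paste(categories, collapse = ", "), call. = FALSE)
  items$unit_cost_kes[sel] <- items$unit_cost_kes[sel] * factor
  items$total_kes <- NULL
  cost_ledger(items, ctx)
}

#' Multi-year enrollment plan for the rollout
#'
#' The base-case program trains counselors once and then runs 12 sites for
#' five years; each site serves 160 participants in its first year and 240
#' in years 2-5, for 13,440 participants in total.
#'
#' @param n_sites Number of sites (default 12).
#' @param participants_per_site_by_year Integer vector, one entry per cost
#'   year (default `c(160, 240, 240, 240, 240)`).
#' @param transport_kes_per_visit Participant transport reimbursement, KES
#'   per visit (default 200).
#' @param visits_per_participant Reimbursed visits per participant (6).
#' @return An object of class `rollout_schedule`.
#' @export
#' @examples
#' total_participants(rollout_schedule())  # 13440
rollout_schedule <- function(n_sites = 12,
                             participants_per_site_by_year =
                               c(160, 240, 240, 240, 240),
                             transport_kes_per_visit = 200,
                             visits_per_participant = 6) {
  if (n_sites < 0 || any(participants_per_site_by_year < 0) ||
      transport_kes_per_visit < 0 || visits_per_participant < 0)
    stop("validation-error: schedule counts and rates must be >= 0",
         call. = FALSE)
  structure(list(n_sites = n_sites,
                 n_cost_years = length(participants_per_site_by_year),
                 participants_per_site_by_year =
                   participants_per_site_by_year,
                 transport_kes_per_visit = transport_kes_per_visit,
                 visits_per_participant = visits_per_participant),
            class = "rollout_schedule")
}

#' Total participants served under a schedule
#' @param sched A [rollout_schedule()].
#' @return Count of participants across all sites and years.
#' @export
total_participants <- function(sched) {
  stopifnot(inherits(sched, "rollout_schedule"))
  sched$n_sites * sum(sched$participants_per_site_by_year)
}

#' Cohort sizes by enrollment year
#' @param sched A [rollout_schedule()].
#' @return Numeric vector: participants enrolled program-wide in each year.
#' @export
cohort_sizes <- function(sched) {
  stopifnot(inherits(sched, "rollout_schedule"))
  sched$n_sites * sched$participants_per_site_by_year
}

#' Nominal program cost stream by year
#'
#' Year 1 carries the full training budget plus one per-site annual budget
#' for every site; years 2 through the last cost year carry the per-site
#' budgets only.
#'
#' @param training,per_site [cost_ledger()]s (USD totals are used).
#' @param sched A [rollout_schedule()].
#' @return A [cash_flow()] in nominal USD by program year.
#' @export
cost_stream <- function(training, per_site, sched) {
  stopifnot(inherits(training, "cost_ledger"),
            inherits(per_site, "cost_ledger"),
            inherits(sched, "rollout_schedule"))
  annual_sites <- sched$n_sites * per_site$grand_total_usd
  amounts <- rep(annual_sites, sched$n_cost_years)
  amounts[1] <- amounts[1] + training$grand_total_usd
  cash_flow(amounts)
}

#' Cost per participant
#'
#' @param total_cost Total program cost in USD (discounted or not, caller's
#'   choice).
#' @param sched A [rollout_schedule()].
#' @return USD per participant.
#' @export
#' @examples
#' unit_cost(585868, rollout_schedule())  # ~43.6
unit_cost <- function(total_cost, sched) {
  n <- total_participants(sched)
  if (n <= 0) {
    if (total_cost == 0) return(0)
    stop("invalid-parameter: schedule has no participants", call. = FALSE)
  }
  total_cost / n
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf("Cost ledger: %d items, KES %s ($%s)\n", nrow(x$items),
              format(round(x$grand_total_kes), big.mark = ","),
              format(round(x$grand_total_usd), big.mark = ",")))
  for (cat_name in names(x$category_subtotals))
    cat(sprintf("  %-28s KES %s\n", cat_name,
                format(round(x$category_subtotals[[cat_name]]),
                       big.mark = ",")))
  invisible(x)
}
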