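#' Path to the bundled base-case configuration
#' @return Path to the YAML file transcribing the base-case inputs.
#' @export
base_config_path <- function() {
  system.file("extdata", "base_case.yaml", package = "taskshiftCBA",
              mustWork = TRUE)
}

#' Load a full model configuration from a YAML file
#'
#' Reads and validates every model input: the economic context (discount
#' rate, exchange rate, CPI table), the model parameters, the rollout
#' schedule, the two cost-ledger CSVs (paths relative to the config file),
#' and the uncertain-input specifications used by the sensitivity analyses.
#' Validation failures name the offending field.
#'
#' @param path YAML configuration file (default the bundled base case).
#' @return List of class `cba_config` with elements `params`, `ctx`,
#'   `sched`, `training`, `per_site`, `specs`, `path`.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$params$delta_abstinence  # 0.31
load_config <- function(path = base_config_path()) {
  if (!file.exists(path))
    stop("parse-error: no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (block in c("economic_context", "model", "schedule", "ledgers"))
    if (is.null(raw[[block]]))
      stop("validation-error: config block '", block, "' is missing",
           call. = FALSE)
  ec <- raw$economic_context
  cpi <- unlist(ec$cpi)
  ctx <- economic_context(discount_rate = ec$discount_rate,
                          exchange_rate = ec$exchange_rate_kes_per_usd,
                          cpi = cpi,
                          reference_year = ec$reference_year)
  m <- raw$model
  params <- model_parameters(
    p_abst_cbt = m$p_abst_cbt, p_abst_uc = m$p_abst_uc,
    alcohol_attrib_frac = m$alcohol_attrib_frac,
    nondrug_costs_2009 = unlist(m$nondrug_costs_2009),
    arv_drug_cost = m$arv_drug_cost,
    adherence_counts = lapply(m$adherence_counts, unlist),
    lfp_rise = m$lfp_rise, lfp_se_hours = m$lfp_se_hours,
    lfp_baseline_hours = m$lfp_baseline_hours,
    monthly_min_wage = m$monthly_min_wage,
    hp_hours_firewood = m$hp_hours_firewood,
    hp_hours_water = m$hp_hours_water,
    hp_se_firewood = m$hp_se_firewood, hp_se_water = m$hp_se_water,
    house_wage = m$house_wage, female_fraction = m$female_fraction,
    effect_length = m$effect_length,
    annualization_weeks = m$annualization_weeks)
  # 2009-denominated costs must be expressible in the reference year
  inflate_cpi(1, 2009, ctx$reference_year, ctx)
  s <- raw$schedule
  sched <- rollout_schedule(
    n_sites = s$n_sites,
    participants_per_site_by_year = unlist(s$participants_per_site_by_year),
    transport_kes_per_visit = s$transport_kes_per_visit,
    visits_per_participant = s$visits_per_participant)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  training <- read_cost_ledger(resolve(raw$ledgers$training), ctx)
  per_site <- read_cost_ledger(resolve(raw$ledgers$per_site), ctx)
  specs <- lapply(raw$sensitivity, function(sp) {
    se <- sp[["se"]]
    if (is.null(se) && !is.null(sp[["se_hours"]]))
      se <- sp[["se_hours"]] / sp[["baseline_hours"]]
    parameter_spec(sp$name, sp$base, sp$low, sp$high,
                   units = if (is.null(sp$units)) "" else sp$units,
                   distribution = sp$distribution, se = se)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(params = params, ctx = ctx, sched = sched,
                 training = training, per_site = per_site,
                 specs = specs, path = path),
            class = "cba_config")
}

#' Write a loaded configuration back to disk
#'
#' Emits a YAML config plus the two ledger CSVs into `dir`; reloading the
#' written config reproduces identical model inputs.
#'
#' @param cfg A `cba_config` from [load_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the written YAML file.
#' @export
write_config <- function(cfg, dir) {
  stopifnot(inherits(cfg, "cba_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_items <- function(ledger, file) {
    items <- ledger$items
    items$total_kes <- NULL
    utils::write.csv(items, file.path(dir, file), row.names = FALSE)
  }
  write_items(cfg$training, "training_costs.csv")
  write_items(cfg$per_site, "site_costs.csv")
  p <- cfg$params
  specs <- lapply(cfg$specs, function(s) {
    out <- list(name = s$name, base = s$base, low = s$low, high = s$high,
                units = s$units, distribution = s$distribution)
    if (!is.na(s$se)) out$se <- s$se
    out
  })
  names(specs) <- NULL
  doc <- list(
    economic_context = list(
      discount_rate = cfg$ctx$discount_rate,
      exchange_rate_kes_per_usd = cfg$ctx$exchange_rate,
      reference_year = cfg$ctx$reference_year,
      cpi = as.list(cfg$ctx$cpi)),
    schedule = list(
      n_sites = cfg$sched$n_sites,
      participants_per_site_by_year =
        cfg$sched$participants_per_site_by_year,
      transport_kes_per_visit = cfg$sched$transport_kes_per_visit,
      visits_per_participant = cfg$sched$visits_per_participant),
    ledgers = list(training = "training_costs.csv",
                   per_site = "site_costs.csv"),
    model = list(
      p_abst_cbt = p$p_abst_cbt, p_abst_uc = p$p_abst_uc,
      alcohol_attrib_frac = p$alcohol_attrib_frac,
      nondrug_costs_2009 = as.list(p$nondrug_costs_2009),
      arv_drug_cost = p$arv_drug_cost,
      adherence_counts = lapply(p$adherence_counts, as.list),
      lfp_rise = p$lfp_rise, lfp_se_hours = p$lfp_se_hours,
      lfp_baseline_hours = p$lfp_baseline_hours,
      monthly_min_wage = p$monthly_min_wage,
      hp_hours_firewood = p$hp_hours_firewood,
      hp_hours_water = p$hp_hours_water,
      hp_se_firewood = p$hp_se_firewood, hp_se_water = p$hp_se_water,
      house_wage = p$house_wage, female_fraction = p$female_fraction,
      effect_length = p$effect_length,
      annualization_weeks = p$annualization_weeks),
    sensitivity = specs)
  out_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(doc, out_path, precision = 15)
  invisible(out_path)
}

#' Uncertain-input specifications at their base-case values
#'
#' One [parameter_spec()] per uncertain model input, with the sensitivity
#' range and distribution family for the probabilistic analysis, read from
#' the bundled base-case configuration.
#'
#' @return Named list of [parameter_spec()]s.
#' @export
base_parameter_specs <- function() {
  load_config()$specs
}

#' Model inputs assembled from a configuration
#' @param cfg A `cba_config` from [load_config()].
#' @return A [model_inputs()] bundle.
#' @export
config_model_inputs <- function(cfg = load_config()) {
  stopifnot(inherits(cfg, "cba_config"))
  model_inputs(cfg$params, cfg$ctx, cfg$training, cfg$per_site, cfg$sched)
}
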