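#' Write analysis results to disk
#'
#' Emits machine-readable reports with deterministic field ordering: a JSON
#' summary plus CSV tables. Monetary totals are reported both at raw
#' precision and at headline precision (totals to the nearest $1,000, BCRs
#' to 2 decimals, per-person values to the cent).
#'
#' @param result A `cba_result`, `tornado_result`, or `psa_result`.
#' @param dir Output directory (created if needed).
#' @param ... Unused.
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(result, dir, ...) UseMethod("write_report")

#' @rdname write_report
#' @export
write_report.cba_result <- function(result, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, "cba_summary.json")
  table_path <- file.path(dir, "cba_per_year.csv")
  jsonlite::write_json(list(
    bcr = result$bcr,
    bcr_rounded = round(result$bcr, 2),
    total_cost_disc = result$total_cost_disc,
    total_cost_disc_rounded = round(result$total_cost_disc / 1000) * 1000,
    total_benefit_disc = result$total_benefit_disc,
    total_benefit_disc_rounded =
      round(result$total_benefit_disc / 1000) * 1000,
    net_benefit = result$net_benefit,
    unit_cost = result$unit_cost,
    unit_cost_disc = result$unit_cost_disc,
    effect_length = result$effect_length,
    discount_rate = result$discount_rate),
    summary_path, auto_unbox = TRUE, digits = NA)
  horizon <- length(result$per_year_benefits$amounts)
  pad <- function(x) c(x, rep(0, horizon - length(x)))
  tab <- data.frame(
    year = seq_len(horizon),
    cost_nominal = pad(result$per_year_costs$amounts),
    cost_discounted = pad(result$per_year_costs_disc$amounts),
    benefit_nominal = result$per_year_benefits$amounts,
    benefit_discounted = result$per_year_benefits_disc$amounts)
  utils::write.csv(tab, table_path, row.names = FALSE)
  invisible(c(summary_path, table_path))
}

#' @rdname write_report
#' @export
write_report.tornado_result <- function(result, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "tornado.csv")
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
write_report.psa_result <- function(result, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "psa_summary.csv")
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  clamps <- attr(result, "clamp_counts")
  files <- path
  if (!is.null(clamps)) {
    cpath <- file.path(dir, "psa_clamp_counts.csv")
    utils::write.csv(data.frame(parameter = names(clamps),
                                clamped_draws = as.integer(clamps)),
                     cpath, row.names = FALSE)
    files <- c(files, cpath)
  }
  draws <- attr(result, "draws")
  if (!is.null(draws)) {
    dpath <- file.path(dir, "psa_replicates.csv")
    long <- do.call(rbind, lapply(names(draws), function(L)
      data.frame(effect_length = as.integer(L), bcr = draws[[L]])))
    utils::write.csv(long, dpath, row.names = FALSE)
    files <- c(files, dpath)
  }
  invisible(files)
}
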