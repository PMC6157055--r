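#' Per-year cost components of a scenario run
#'
#' Tabular equivalent of the cost-components figure: medication,
#' diagnostic aids and complication treatment per year, with their total.
#' Totals equal the run's cost-breakdown totals exactly.
#'
#' @param run A `bia_run`.
#' @return Data frame: `year`, `medication_usd`, `diagnostics_usd`,
#'   `complications_usd`, `total_usd`.
#' @export
cost_component_table <- function(run) {
  stopifnot(inherits(run, "bia_run"))
  cc <- run$costs
  data.frame(year = cc$year,
             medication_usd = cc$medication_usd,
             diagnostics_usd = cc$diagnostics_usd,
             complications_usd = cc$ami_usd + cc$stroke_usd + cc$hf_usd,
             total_usd = cc$total_usd)
}

#' Per-outcome, per-scenario, per-year event counts
#'
#' Tabular equivalent of the cardiovascular-events figure: expected
#' counts of AMI, stroke, heart failure and cardiovascular death under
#' each scenario and year, in long format.
#'
#' @param baseline,new `bia_run` objects.
#' @return Long data frame: `outcome`, `scenario`, `year`, `count`.
#' @export
event_table <- function(baseline, new) {
  stopifnot(inherits(baseline, "bia_run"), inherits(new, "bia_run"))
  reshape_run <- function(run) {
    ev <- run$events
    do.call(rbind, lapply(.outcomes, function(o) {
      data.frame(outcome = o, scenario = ev$scenario, year = ev$year,
                 count = ev[[o]], stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(reshape_run(baseline), reshape_run(new))
  rownames(out) <- NULL
  out
}

#' Binned PSA cost differences for plotting
#'
#' Histogram data of the per-iteration cost differences (new minus
#' baseline): bin edges and counts, with counts summing to the number of
#' iterations. The mass below zero equals the fraction of cost-saving
#' iterations.
#'
#' @param psa A `bia_psa`.
#' @param year A horizon year (as character or number) or `"total"`.
#' @param breaks Passed to [graphics::hist()] breaks logic via
#'   [base::cut()]-free binning (a count of equal-width bins).
#' @return List: `year`, `bin_edges`, `counts`.
#' @export
psa_histogram_data <- function(psa, year = "total", breaks = 30) {
  stopifnot(inherits(psa, "bia_psa"))
  col <- as.character(year)
  if (!col %in% names(psa$draws)) stop("no PSA draws for '", col, "'")
  x <- psa$draws[[col]]
  if (length(unique(x)) == 1) {
    edges <- c(x[1] - 0.5, x[1] + 0.5)
    counts <- length(x)
  } else {
    edges <- seq(min(x), max(x), length.out = breaks + 1)
    idx <- findInterval(x, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(idx, nbins = breaks)
  }
  list(year = col, bin_edges = edges, counts = counts)
}

#' Assemble a run report
#'
#' A self-describing summary of a deterministic comparison (and
#' optionally a PSA): parameter provenance, per-year cost and event
#' tables, the budget impact, and the PSA summary.
#'
#' @param baseline,new `bia_run` objects.
#' @param impact A `bia_budget_impact`.
#' @param psa Optional `bia_psa`.
#' @param params_file Parameter file path recorded as provenance.
#' @param policy Reconciliation policy recorded as provenance.
#' @param seed Seed recorded as provenance.
#' @return A `bia_report` list.
#' @export
run_report <- function(baseline, new, impact, psa = NULL,
                       params_file = default_parameter_file(),
                       policy = "point_estimate", seed = NA_integer_) {
  structure(list(
    schema_version = "1.0",
    provenance = list(params_file = params_file, policy = policy,
                      seed = seed),
    costs_baseline = cost_component_table(baseline),
    costs_new = cost_component_table(new),
    events = event_table(baseline, new),
    budget_impact = list(by_year = impact$by_year,
                         real_terms = impact$real_terms,
                         total_difference_usd = impact$total_difference),
    psa = if (is.null(psa)) NULL else list(
      n_iterations = psa$n_iterations, seed = psa$seed,
      policy = psa$policy,
      fraction_saving = as.list(psa$fraction_saving),
      quantiles_total_usd = as.list(psa$quantiles))
  ), class = "bia_report")
}

#' Write a run report as JSON
#'
#' @param report A `bia_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "bia_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       dataframe = "rows")
  invisible(path)
}
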