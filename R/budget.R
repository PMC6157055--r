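`%||%` <- function(x, y) if (is.null(x)) y else x

# In the PSA, scenario fields that mirror sampled parameters are refreshed
# from the iteration's draws: the treated regime selects its tablet count,
# established patients use the old-guideline adherence, and the newly
# classified stratum (present when the scenario carries an established
# rule) uses the new-stratum adherence.
.apply_values_to_scenario <- function(scenario, v) {
  scenario$tablets_per_day <-
    if (scenario$event_probability_set == "intensive") {
      v$tablets_intensive
    } else {
      v$tablets_standard
    }
  scenario$adherence_established <- min(1, max(0, v$adherence_old))
  if (!is.null(scenario$established_rule)) {
    scenario$adherence_new_stratum <- min(1, max(0, v$adherence_new))
  }
  scenario
}

#' Run one scenario deterministically over the horizon
#'
#' Chains, for each horizon year: prevalence estimation, the
#' prescription/adherence partition, expected cardiovascular events,
#' the cost breakdown, and survivor carry-over into the next year.
#' The run is deterministic: identical inputs give identical outputs.
#'
#' @param scenario A `bia_scenario`.
#' @param params A `bia_params` object.
#' @param projection Population projection (see [generate_population()]).
#' @param untreated_cvdeath Fallback rule for the untreated
#'   cardiovascular-death probability (see [event_probabilities()]).
#' @param values Optional flat list of parameter values overriding the
#'   point estimates (used by the PSA to inject sampled draws).
#' @return A `bia_run`: data frames `states`, `events`, `costs`, one row
#'   per horizon year.
#' @export
run_scenario <- function(scenario, params, projection,
                         untreated_cvdeath = c("standard", "zero"),
                         values = NULL) {
  stopifnot(inherits(scenario, "bia_scenario"),
            inherits(params, "bia_params"))
  untreated_cvdeath <- match.arg(untreated_cvdeath)
  v <- values %||% .parameter_values(params)
  probs <- event_probabilities(v, untreated_cvdeath)
  regime <- scenario$event_probability_set
  years <- params$horizon_years
  states <- vector("list", length(years))
  events <- vector("list", length(years))
  costs <- vector("list", length(years))
  state <- NULL
  deaths <- 0
  for (i in seq_along(years)) {
    y <- years[i]
    prev <- estimate_prevalent_population(projection, scenario, y)
    n_new <- if (!is.null(scenario$established_rule)) {
      est <- .prevalence_from_rule(scenario$established_rule, projection, y)
      max(0, prev - est)
    } else 0
    state <- if (i == 1) {
      partition_treatment(prev, n_new, v$physician_prescription,
                          scenario$adherence_established,
                          scenario$adherence_new_stratum,
                          year = y, scenario = scenario$name)
    } else {
      advance_year(state, deaths, prev, n_new, v$physician_prescription,
                   scenario$adherence_established,
                   scenario$adherence_new_stratum)
    }
    ev <- expected_events(state, probs, regime)
    deaths <- min(round(ev$cvdeath), state$n_hypertensive)
    states[[i]] <- as.data.frame(unclass(state),
                                 stringsAsFactors = FALSE)
    events[[i]] <- ev
    costs[[i]] <- cost_breakdown(state, ev, v, scenario)
  }
  structure(list(scenario = scenario,
                 states = do.call(rbind, states),
                 events = do.call(rbind, events),
                 costs = do.call(rbind, costs)),
            class = "bia_run")
}

#' @export
print.bia_run <- function(x, ...) {
  cat("Scenario run:", x$scenario$name, "\n")
  print(x$costs, row.names = FALSE)
  invisible(x)
}

#' Budget impact of the new scenario relative to baseline
#'
#' The budget impact is the difference in total medical care costs
#' between the two scenarios, per year and over the horizon; negative
#' differences are savings. Horizon totals can be expressed in base-year
#' real terms by CPI deflation.
#'
#' @param baseline,new `bia_run` objects over the same years.
#' @param real_terms Deflate each year to base-year terms before summing
#'   horizon totals.
#' @param cpi_by_year CPI series for deflation (required when
#'   `real_terms = TRUE`).
#' @return A `bia_budget_impact`: `$by_year` (totals and difference per
#'   year), `$total_baseline`, `$total_new`, `$total_difference`.
#' @export
budget_impact <- function(baseline, new, real_terms = FALSE,
                          cpi_by_year = NULL) {
  stopifnot(inherits(baseline, "bia_run"), inherits(new, "bia_run"))
  if (!identical(baseline$costs$year, new$costs$year)) {
    stop("scenario runs cover different years")
  }
  years <- baseline$costs$year
  b <- baseline$costs$total_usd
  n <- new$costs$total_usd
  if (real_terms) {
    if (is.null(cpi_by_year)) stop("real_terms needs cpi_by_year")
    b_adj <- mapply(deflate, b, years,
                    MoreArgs = list(cpi_by_year = cpi_by_year))
    n_adj <- mapply(deflate, n, years,
                    MoreArgs = list(cpi_by_year = cpi_by_year))
  } else {
    b_adj <- b
    n_adj <- n
  }
  by_year <- data.frame(year = years, baseline_usd = b, new_usd = n,
                        difference_usd = n - b)
  structure(list(by_year = by_year,
                 real_terms = real_terms,
                 total_baseline = sum(b_adj),
                 total_new = sum(n_adj),
                 total_difference = sum(n_adj) - sum(b_adj)),
            class = "bia_budget_impact")
}

#' @export
print.bia_budget_impact <- function(x, ...) {
  cat("Budget impact (new - baseline), USD",
      if (x$real_terms) "[base-year real terms]" else "[nominal]", "\n")
  print(x$by_year, row.names = FALSE)
  cat(sprintf("Horizon total: %s (%s)\n",
              format(round(x$total_difference), big.mark = ","),
              if (x$total_difference < 0) "saving" else "added cost"))
  invisible(x)
}

#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' Each iteration draws one value per distribution-tagged parameter
#' (draws are shared between the two scenarios, so the comparison within
#' an iteration uses common random parameters), runs both scenarios
#' deterministically under those values, and records the cost difference
#' per year and over the horizon. Per-iteration substream seeds are
#' derived deterministically from the root seed, so results are
#' reproducible and independent of iteration order.
#'
#' @param params A `bia_params` object.
#' @param scenarios List with elements `baseline` and `new`
#'   (`bia_scenario` objects).
#' @param projection Population projection.
#' @param n_iter Iterations (default: the parameter file's
#'   `psa_iterations`).
#' @param seed Root seed.
#' @param policy Reconciliation policy applied to the distributions before
#'   sampling (see [reconcile()]); the default rescales each distribution
#'   so its mean matches the printed point estimate.
#' @param untreated_cvdeath See [event_probabilities()].
#' @return A `bia_psa`: `$draws` (per-iteration differences, one column
#'   per year plus `total`), `$fraction_saving` (per year and pooled over
#'   the horizon total), `$quantiles` of the horizon difference,
#'   `$n_iterations`, `$seed`, `$policy`.
#' @export
run_psa <- function(params, scenarios, projection,
                    n_iter = params$psa_iterations, seed = 1L,
                    policy = "rescaled_distribution",
                    untreated_cvdeath = c("standard", "zero")) {
  stopifnot(inherits(params, "bia_params"), n_iter >= 1)
  untreated_cvdeath <- match.arg(untreated_cvdeath)
  ps <- reconcile_parameters(params, policy)
  years <- ps$horizon_years
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = length(years) + 1,
                  dimnames = list(NULL, c(years, "total")))
  for (j in seq_len(n_iter)) {
    set.seed(iter_seeds[j])
    v <- .sample_parameter_values(ps)
    sb <- .apply_values_to_scenario(scenarios$baseline, v)
    sn <- .apply_values_to_scenario(scenarios$new, v)
    rb <- tryCatch(
      run_scenario(sb, ps, projection, untreated_cvdeath, values = v),
      error = function(e) {
        stop("PSA iteration ", j, " (seed ", iter_seeds[j],
             ") failed in baseline scenario: ", conditionMessage(e))
      })
    rn <- tryCatch(
      run_scenario(sn, ps, projection, untreated_cvdeath, values = v),
      error = function(e) {
        stop("PSA iteration ", j, " (seed ", iter_seeds[j],
             ") failed in new scenario: ", conditionMessage(e))
      })
    d <- rn$costs$total_usd - rb$costs$total_usd
    draws[j, ] <- c(d, sum(d))
  }
  frac <- colMeans(draws < 0)
  structure(list(draws = as.data.frame(draws, check.names = FALSE),
                 fraction_saving = frac,
                 quantiles = stats::quantile(
                   draws[, "total"],
                   probs = c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 n_iterations = n_iter, seed = seed, policy = policy),
            class = "bia_psa")
}

#' @export
print.bia_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_iterations,
      "iterations (seed", x$seed, ", policy", x$policy, ")\n")
  cat("Fraction of cost-saving iterations:\n")
  print(round(x$fraction_saving, 4))
  cat("Horizon difference quantiles (USD):\n")
  print(round(x$quantiles))
  invisible(x)
}
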