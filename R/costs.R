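#' Annual antihypertensive medication cost
#'
#' `n_treated * tablets_per_day * daily_cost_per_tablet * 365`, in USD.
#'
#' @param n_treated Treated (prescribed and adherent) patients.
#' @param tablets_per_day Mean daily tablets of the regime.
#' @param daily_cost_per_tablet USD per tablet-day.
#' @return USD per year.
#' @export
medication_cost <- function(n_treated, tablets_per_day,
                            daily_cost_per_tablet) {
  stopifnot(n_treated >= 0, tablets_per_day >= 0,
            daily_cost_per_tablet >= 0)
  n_treated * tablets_per_day * daily_cost_per_tablet * 365
}

#' Annual diagnostic-aid cost
#'
#' The diagnostic panel (blood chemistry, ECG, lipid profile, ...) is
#' prescribed `annual_frequency` times per year to every diagnosed
#' hypertensive, treated or not.
#'
#' @param n_diagnosed Diagnosed hypertensives.
#' @param annual_frequency Mean panels per patient-year.
#' @param unit_cost USD per panel.
#' @return USD per year.
#' @export
diagnostics_cost <- function(n_diagnosed, annual_frequency, unit_cost) {
  stopifnot(n_diagnosed >= 0, annual_frequency >= 0, unit_cost >= 0)
  n_diagnosed * annual_frequency * unit_cost
}

#' Cost of cardiovascular complications for a year's expected events
#'
#' AMI episodes are priced at the year-specific published cost; stroke at
#' its per-episode cost; each incident heart-failure case incurs the mean
#' number of decompensation episodes at the per-episode hospital cost plus
#' one year of chronic outpatient management. Deaths carry no direct cost.
#'
#' @param events Event counts (row from [expected_events()]).
#' @param params A `bia_params` object or flat list of parameter values.
#' @param year Calendar year (selects the AMI episode cost).
#' @return Named list: `ami_usd`, `stroke_usd`, `hf_usd`.
#' @export
complication_cost <- function(events, params, year) {
  v <- if (inherits(params, "bia_params")) .parameter_values(params)
       else params
  ami_cost <- v$ami_episode_cost
  if (length(ami_cost) > 1) {
    ami_cost <- unname(ami_cost[as.character(year)])[1]
    if (is.null(ami_cost) || is.na(ami_cost)) {
      stop("no AMI episode cost for year ", year)
    }
  }
  counts <- if (is.data.frame(events)) unlist(events[1, .outcomes])
            else events[.outcomes]
  hf_per_case <- v$hf_decompensations * v$hf_decompensation_cost +
    v$hf_chronic_cost
  list(ami_usd = unname(counts["ami"] * ami_cost),
       stroke_usd = unname(counts["stroke"] * v$stroke_episode_cost),
       hf_usd = unname(counts["hf"] * hf_per_case))
}

#' Deflate a nominal amount to base-year real terms
#'
#' Divides by the compound consumer-price-index growth accumulated after
#' the base year up to and including `year`:
#' `amount / prod(1 + cpi/100)`. Base-year amounts are unchanged. Passing
#' `inflate = TRUE` applies the inverse (nominal terms forward from the
#' base year).
#'
#' @param amount Nominal USD.
#' @param year Calendar year of the amount.
#' @param cpi_by_year Named vector of annual CPI growth rates in percent
#'   (e.g. `c("2018" = 3.95, "2019" = 4.35)`).
#' @param base_year Base year (defaults to the earliest CPI year).
#' @param inflate Apply the inverse transformation.
#' @return Real USD in base-year terms.
#' @export
deflate <- function(amount, year, cpi_by_year,
                    base_year = min(as.integer(names(cpi_by_year))),
                    inflate = FALSE) {
  year <- as.integer(year)
  if (year == base_year) return(amount)
  span <- seq(base_year + 1L, year)
  cpi <- cpi_by_year[as.character(span)]
  if (anyNA(cpi)) {
    stop("CPI missing for year(s) ",
         paste(span[is.na(cpi)], collapse = ", "))
  }
  deflator <- prod(1 + cpi / 100)
  if (inflate) amount * deflator else amount / deflator
}

#' Assemble the cost breakdown of a scenario-year
#'
#' @param state A `bia_cohort_state`.
#' @param events Matching event counts.
#' @param params `bia_params` or flat value list.
#' @param scenario Scenario spec (supplies tablets per day) or a tablets
#'   value via `tablets_per_day`.
#' @param tablets_per_day Overrides the scenario's tablet count.
#' @return One-row data frame: `year`, `scenario`, `medication_usd`,
#'   `diagnostics_usd`, `ami_usd`, `stroke_usd`, `hf_usd`, `total_usd`
#'   (exact component sum).
#' @export
cost_breakdown <- function(state, events, params, scenario = NULL,
                           tablets_per_day = NULL) {
  v <- if (inherits(params, "bia_params")) .parameter_values(params)
       else params
  if (is.null(tablets_per_day)) tablets_per_day <- scenario$tablets_per_day
  med <- medication_cost(state$n_treated, tablets_per_day,
                         v$medication_daily_cost)
  diag <- diagnostics_cost(state$n_hypertensive, v$diagnostic_frequency,
                           v$diagnostics_cost)
  comp <- complication_cost(events, v, state$year)
  out <- data.frame(year = state$year, scenario = state$scenario,
                    medication_usd = med, diagnostics_usd = diag,
                    ami_usd = comp$ami_usd, stroke_usd = comp$stroke_usd,
                    hf_usd = comp$hf_usd)
  out$total_usd <- out$medication_usd + out$diagnostics_usd +
    out$ami_usd + out$stroke_usd + out$hf_usd
  out
}
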