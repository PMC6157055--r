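#' Define a guideline scenario
#'
#' A scenario fixes the diagnostic cut-off, the treatment goal (hence which
#' event-probability regime treated patients follow and how many tablets
#' they take), the adherence probabilities, and the rule that determines
#' the prevalent hypertensive population each year.
#'
#' Prevalence rules:
#' \describe{
#'   \item{fixed rate}{`prevalence_rule = list(type = "fixed_rate",
#'     rate = 0.072)` - rate times the over-20 total.}
#'   \item{age-weighted}{`list(type = "age_weighted", table = <prevalence
#'     table>)` - sum of age-group count x proportion.}
#'   \item{override}{`list(type = "override", counts = c("2018" =
#'     8675154))` - absolute counts; years not supplied are scaled from
#'     the latest supplied year by the projection's population growth.}
#' }
#'
#' @param name Scenario label, e.g. `"baseline"` or `"new"`.
#' @param diagnostic_cutoff `"140/90"` or `"130/80"`.
#' @param treatment_goal `"SBP<140"` or `"SBP<120"`.
#' @param prevalence_rule Prevalence rule (see Details).
#' @param adherence_established Adherence probability of patients above the
#'   old cut-off.
#' @param adherence_new_stratum Adherence probability of the newly
#'   classified 130-139/80-89 stratum (new scenario only).
#' @param tablets_per_day Mean daily tablets of treated patients.
#' @param event_probability_set `"standard"` or `"intensive"`: regime of
#'   treated patients.
#' @param established_rule For the new scenario: the baseline scenario's
#'   prevalence rule, used to size the established stratum; the newly
#'   classified stratum is the excess of this scenario's prevalents over
#'   the established ones.
#' @return A `bia_scenario` object.
#' @export
scenario_spec <- function(name, diagnostic_cutoff, treatment_goal,
                          prevalence_rule, adherence_established,
                          adherence_new_stratum = 0, tablets_per_day,
                          event_probability_set = c("standard",
                                                    "intensive"),
                          established_rule = NULL) {
  event_probability_set <- match.arg(event_probability_set)
  stopifnot(adherence_established >= 0, adherence_established <= 1,
            adherence_new_stratum >= 0, adherence_new_stratum <= 1,
            tablets_per_day > 0)
  structure(list(name = name, diagnostic_cutoff = diagnostic_cutoff,
                 treatment_goal = treatment_goal,
                 prevalence_rule = prevalence_rule,
                 adherence_established = adherence_established,
                 adherence_new_stratum = adherence_new_stratum,
                 tablets_per_day = tablets_per_day,
                 event_probability_set = event_probability_set,
                 established_rule = established_rule),
            class = "bia_scenario")
}

#' Convenience constructors for the two published scenarios
#'
#' The baseline scenario diagnoses at 140/90 mmHg and treats to SBP < 140
#' (standard control, 1.8 tablets/day); the new scenario diagnoses at
#' 130/80 and treats to SBP < 120 (intensive control, 2.8 tablets/day),
#' with the newly classified stratum adhering at the lower published
#' probability.
#'
#' @param params A `bia_params` object.
#' @param prevalence_rule Prevalence rule for this scenario.
#' @param established_rule Baseline prevalence rule (new scenario only).
#' @return A `bia_scenario`.
#' @name canonical_scenarios
NULL

#' @rdname canonical_scenarios
#' @export
baseline_scenario <- function(params, prevalence_rule) {
  scenario_spec("baseline", "140/90", "SBP<140", prevalence_rule,
                adherence_established = param_value(params,
                                                    "adherence_old"),
                tablets_per_day = param_value(params, "tablets_standard"),
                event_probability_set = "standard")
}

#' @rdname canonical_scenarios
#' @export
new_scenario <- function(params, prevalence_rule, established_rule) {
  scenario_spec("new", "130/80", "SBP<120", prevalence_rule,
                adherence_established = param_value(params,
                                                    "adherence_old"),
                adherence_new_stratum = param_value(params,
                                                    "adherence_new"),
                tablets_per_day = param_value(params, "tablets_intensive"),
                event_probability_set = "intensive",
                established_rule = established_rule)
}

.prevalence_from_rule <- function(rule, projection, year) {
  switch(rule$type,
    fixed_rate = round(population_total(projection, year) * rule$rate),
    age_weighted = {
      rows <- projection[projection$year == year, , drop = FALSE]
      if (nrow(rows) == 0) stop("projection does not cover year ", year)
      prop <- rule$table$proportion_hypertensive[
        match(rows$age_group, rule$table$age_group)]
      if (anyNA(prop)) stop("prevalence table missing age groups")
      round(sum(rows$count * prop))
    },
    override = {
      counts <- rule$counts
      y <- as.character(year)
      if (y %in% names(counts)) return(unname(counts[y]))
      if (is.null(projection)) stop("year ", year, " absent from override")
      # scale the latest supplied count by the projection's growth
      have <- as.integer(names(counts))
      ref <- max(have[have < year], have)[1]
      if (is.na(ref)) stop("year ", year, " absent from override")
      scale <- population_total(projection, year) /
        population_total(projection, ref)
      round(unname(counts[as.character(ref)]) * scale)
    },
    stop("unknown prevalence rule type '", rule$type, "'"))
}

#' Prevalent hypertensive population for a scenario-year
#'
#' @param projection Population projection (see [generate_population()]).
#' @param scenario A `bia_scenario`.
#' @param year Calendar year.
#' @return Integer count of prevalent hypertensives.
#' @export
estimate_prevalent_population <- function(projection, scenario, year) {
  .prevalence_from_rule(scenario$prevalence_rule, projection, year)
}

#' Split prevalent hypertensives into treated and untreated compartments
#'
#' Applies the prescription/adherence cascade: treated patients are those
#' whose physician prescribes per guideline and who adhere. The newly
#' classified stratum uses its own (lower) adherence probability.
#' Diagnosed-but-unprescribed and prescribed-but-non-adherent patients are
#' pooled as untreated. Counts are rounded half-to-even at compartment
#' boundaries and the rounding residual is assigned to the untreated
#' compartment, so treated + untreated = hypertensive exactly.
#'
#' @param n_hypertensive Prevalent hypertensives.
#' @param n_new_stratum Members of the newly classified 130-139/80-89
#'   stratum (0 in the baseline scenario).
#' @param physician_p Physician prescription probability.
#' @param adherence_old Adherence of established hypertensives.
#' @param adherence_new Adherence of the new stratum.
#' @param year Calendar year recorded on the state.
#' @param scenario Scenario label recorded on the state.
#' @return A `bia_cohort_state`: counts `n_hypertensive`, `n_prescribed`,
#'   `n_treated`, `n_untreated`, `n_new_stratum`.
#' @export
partition_treatment <- function(n_hypertensive, n_new_stratum = 0,
                                physician_p, adherence_old,
                                adherence_new = 0, year = NA_integer_,
                                scenario = NA_character_) {
  stopifnot(n_new_stratum <= n_hypertensive, n_new_stratum >= 0,
            physician_p >= 0, physician_p <= 1)
  n_est <- n_hypertensive - n_new_stratum
  prescribed <- round(n_est * physician_p) +
    round(n_new_stratum * physician_p)
  treated <- round(n_est * physician_p * adherence_old) +
    round(n_new_stratum * physician_p * adherence_new)
  structure(list(year = year, scenario = scenario,
                 n_hypertensive = n_hypertensive,
                 n_prescribed = prescribed,
                 n_treated = treated,
                 n_untreated = n_hypertensive - treated,
                 n_new_stratum = n_new_stratum),
            class = "bia_cohort_state")
}

#' @export
print.bia_cohort_state <- function(x, ...) {
  cat(sprintf(
    "%s %s: hypertensive %s | treated %s | untreated %s | new stratum %s\n",
    x$scenario, x$year, format(x$n_hypertensive, big.mark = ","),
    format(x$n_treated, big.mark = ","),
    format(x$n_untreated, big.mark = ","),
    format(x$n_new_stratum, big.mark = ",")))
  invisible(x)
}

#' Advance the cohort one year with survivor carry-over
#'
#' Treated patients who survive the year are added to the next year's
#' prevalent pool (early treatment improves survival, so survivors remain
#' in care). Deaths are attributed to the treated compartment in
#' proportion to its size. Everyone is then re-partitioned through the
#' prescription/adherence cascade for the new year.
#'
#' @param state Current `bia_cohort_state`.
#' @param deaths Cardiovascular deaths during the current year.
#' @param next_year_prevalent Rule-based prevalent count for the next year
#'   (before carry-over).
#' @param n_new_stratum Next year's newly classified stratum.
#' @param physician_p,adherence_old,adherence_new Cascade probabilities for
#'   the re-partition.
#' @return Next year's `bia_cohort_state`.
#' @export
advance_year <- function(state, deaths, next_year_prevalent,
                         n_new_stratum = 0, physician_p, adherence_old,
                         adherence_new = 0) {
  stopifnot(inherits(state, "bia_cohort_state"),
            deaths <= state$n_hypertensive)
  treated_deaths <- if (state$n_hypertensive > 0) {
    round(deaths * state$n_treated / state$n_hypertensive)
  } else 0
  carry <- state$n_treated - treated_deaths
  n_next <- next_year_prevalent + carry
  if (n_next < 0) {
    warning("carry-over produced a negative prevalent count; clamped to 0")
    n_next <- 0
  }
  partition_treatment(n_next, min(n_new_stratum, n_next), physician_p,
                      adherence_old, adherence_new,
                      year = if (is.na(state$year)) NA_integer_ else
                        state$year + 1L,
                      scenario = state$scenario)
}
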