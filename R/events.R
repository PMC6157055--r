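.outcomes <- c("ami", "stroke", "hf", "cvdeath")

#' Annual event probabilities by treatment regime
#'
#' Assembles the per-regime annual probabilities of acute myocardial
#' infarction (AMI), stroke, heart failure (HF) and cardiovascular death
#' from a parameter set (or a flat list of parameter values, as used
#' inside the PSA). The published table carries no cardiovascular-death
#' probability for untreated patients; by default the standard-control
#' probability is used as a conservative fallback (deaths drive survivor
#' carry-over, so some value is required), or it can be set to zero.
#'
#' @param params A `bia_params` object or flat named list of values.
#' @param untreated_cvdeath `"standard"` (default fallback) or `"zero"`.
#' @return List of regimes `standard`, `intensive`, `untreated`, each a
#'   named vector over `ami`, `stroke`, `hf`, `cvdeath`.
#' @export
event_probabilities <- function(params,
                                untreated_cvdeath = c("standard", "zero")) {
  untreated_cvdeath <- match.arg(untreated_cvdeath)
  v <- if (inherits(params, "bia_params")) .parameter_values(params)
       else params
  pick <- function(reg) c(ami = v[[paste0("p_ami_", reg)]],
                          stroke = v[[paste0("p_stroke_", reg)]],
                          hf = v[[paste0("p_hf_", reg)]],
                          cvdeath = v[[paste0("p_cvdeath_", reg)]])
  untr <- pick("untreated")
  untr["cvdeath"] <- if (untreated_cvdeath == "standard") {
    v[["p_cvdeath_standard"]]
  } else 0
  list(standard = pick("standard"), intensive = pick("intensive"),
       untreated = untr)
}

#' Expected annual cardiovascular events for a cohort state
#'
#' Each outcome's expected count is `n_treated * p(regime) + n_untreated *
#' p(untreated)`. Counts are expected values (real numbers), not sampled:
#' the cohort model is deterministic given its parameters, with
#' uncertainty handled only in the PSA. Outcomes are treated as
#' independent (no competing risks).
#'
#' @param state A `bia_cohort_state`.
#' @param probs Regime probabilities from [event_probabilities()].
#' @param treated_regime `"standard"` or `"intensive"`.
#' @return One-row data frame: `year`, `scenario`, `ami`, `stroke`, `hf`,
#'   `cvdeath`.
#' @export
expected_events <- function(state, probs,
                            treated_regime = c("standard", "intensive")) {
  treated_regime <- match.arg(treated_regime)
  pt <- probs[[treated_regime]]
  pu <- probs$untreated
  counts <- state$n_treated * pt[.outcomes] +
    state$n_untreated * pu[.outcomes]
  out <- data.frame(year = state$year, scenario = state$scenario,
                    t(counts))
  names(out) <- c("year", "scenario", .outcomes)
  out
}

#' Hazard ratio between two arms from cumulative incidence
#'
#' Converts each arm's annual cumulative incidence to a hazard via
#' `-log(1 - r)` and returns the per-outcome ratio
#' `log(1 - r_a) / log(1 - r_b)`. Identical arms give exactly 1; a zero
#' rate in the reference arm makes the ratio undefined (`NA`).
#'
#' @param events_a,events_b Event counts (rows from [expected_events()] or
#'   named vectors over the outcomes).
#' @param exposure_a,exposure_b Population at risk in each arm.
#' @return Named numeric vector of hazard ratios per outcome.
#' @export
hazard_ratio <- function(events_a, exposure_a, events_b, exposure_b) {
  stopifnot(exposure_a > 0, exposure_b > 0)
  get_counts <- function(e) {
    if (is.data.frame(e)) unlist(e[1, .outcomes]) else e[.outcomes]
  }
  ra <- get_counts(events_a) / exposure_a
  rb <- get_counts(events_b) / exposure_b
  if (any(ra > 1 | rb > 1, na.rm = TRUE)) {
    stop("events exceed exposure")
  }
  hr <- ifelse(rb == 0, NA_real_, log1p(-ra) / log1p(-rb))
  names(hr) <- .outcomes
  hr
}

#' Annualize a cumulative event probability
#'
#' Converts `events / n` observed over `followup_years` of follow-up to a
#' constant annual probability: `1 - (1 - events/n)^(1/followup_years)`.
#' This is how trial event counts (the Beta shape parameters of the
#' sensitivity distributions) relate to the table's annual point
#' estimates.
#'
#' @param events Events observed.
#' @param n Population at risk.
#' @param followup_years Follow-up duration in years.
#' @return Annual probability.
#' @export
annualize_probability <- function(events, n, followup_years) {
  stopifnot(followup_years > 0, n > 0, events >= 0)
  if (events > n) stop("events cannot exceed n")
  1 - (1 - events / n)^(1 / followup_years)
}
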