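# Canonical parameter registry. `kind` drives range validation:
# probabilities must lie in [0,1], costs/counts must be non-negative.
.bia_param_registry <- data.frame(
  name = c(
    "physician_prescription", "adherence_old", "adherence_new",
    "p_ami_standard", "p_stroke_standard", "p_hf_standard",
    "p_cvdeath_standard",
    "p_ami_intensive", "p_stroke_intensive", "p_hf_intensive",
    "p_cvdeath_intensive",
    "p_ami_untreated", "p_stroke_untreated", "p_hf_untreated",
    "tablets_intensive", "tablets_standard",
    "diagnostic_frequency", "hf_decompensations",
    "medication_daily_cost", "diagnostics_cost",
    "ami_episode_cost", "stroke_episode_cost",
    "hf_decompensation_cost", "hf_chronic_cost"),
  kind = c(rep("probability", 14), rep("count", 4), rep("cost", 6)),
  stringsAsFactors = FALSE
)

#' Canonical parameter names
#'
#' The model's parameter table, one canonical name per published row (the
#' three year-specific AMI episode costs form a single parameter with a
#' per-year estimate).
#'
#' @return Character vector of the 24 canonical parameter names.
#' @export
parameter_names <- function() .bia_param_registry$name

.bia_globals <- c("baseline_prevalence", "horizon_years", "cpi_by_year",
                  "fx_cop_per_usd", "psa_iterations")

#' Path to the packaged parameter fixture
#'
#' The shipped YAML file reproduces the published model-parameter table
#' (point estimates, units and PSA distributions) together with the global
#' settings: baseline prevalence 7.2%, horizon 2018-2020, annual CPI growth
#' rates, the COP/USD exchange rate and the default PSA iteration count.
#'
#' @return File path of `table1_params.yaml` inside the installed package.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "table1_params.yaml", package = "bpimpact",
              mustWork = TRUE)
}

.as_dist <- function(x, name) {
  if (is.null(x)) return(NULL)
  kind <- x$kind
  if (is.null(kind)) stop("distribution of '", name, "' lacks a kind")
  switch(kind,
    beta = dist_beta(x$a, x$b),
    poisson = dist_poisson(x$lambda),
    gamma = dist_gamma(x$shape, x$scale,
                       currency = if (is.null(x$currency)) "USD"
                                  else x$currency),
    fixed = dist_fixed(x$value),
    stop("unknown distribution kind '", kind, "' for parameter '",
         name, "'"))
}

.new_parameter <- function(name, estimate, units = "", dist = NULL,
                           note = "") {
  structure(list(name = name, estimate = estimate, units = units,
                 dist = dist, note = note),
            class = "bia_parameter")
}

.validate_parameter <- function(p) {
  kind <- .bia_param_registry$kind[match(p$name, .bia_param_registry$name)]
  est <- unlist(p$estimate)
  if (!is.na(kind)) {
    if (kind == "probability" && any(est < 0 | est > 1)) {
      stop("parameter '", p$name, "' is a probability but its estimate ",
           "lies outside [0, 1]")
    }
    if (kind %in% c("cost", "count") && any(est < 0)) {
      stop("parameter '", p$name, "' must be non-negative")
    }
  }
  invisible(p)
}

#' Load a parameter set
#'
#' Reads the flat YAML schema documented in the packaged fixture: a
#' `globals` mapping (prevalence, horizon, CPI series, exchange rate,
#' PSA iterations) and a `parameters` mapping from canonical name to
#' `{estimate, units, dist, note}`. The AMI episode cost carries a per-year
#' estimate mapping.
#'
#' @param path YAML file; defaults to the packaged fixture.
#' @return A `bia_params` object: `$parameters` (named list of
#'   `bia_parameter`), plus the global settings.
#' @export
load_parameters <- function(path = default_parameter_file()) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed parameter file '", path, "': ", conditionMessage(e))
  })
  missing_g <- setdiff(.bia_globals, names(raw$globals))
  if (length(missing_g)) {
    stop("parameter file is missing global settings: ",
         paste(missing_g, collapse = ", "))
  }
  missing_p <- setdiff(parameter_names(), names(raw$parameters))
  if (length(missing_p)) {
    stop("parameter file is missing mandatory parameters: ",
         paste(missing_p, collapse = ", "))
  }
  params <- lapply(parameter_names(), function(nm) {
    row <- raw$parameters[[nm]]
    if (is.null(row$estimate)) {
      stop("parameter '", nm, "' has no estimate")
    }
    est <- row$estimate
    if (is.list(est)) est <- unlist(est)  # per-year mapping
    p <- .new_parameter(nm, est,
                        units = if (is.null(row$units)) "" else row$units,
                        dist = .as_dist(row$dist, nm),
                        note = if (is.null(row$note)) "" else row$note)
    .validate_parameter(p)
  })
  names(params) <- parameter_names()
  g <- raw$globals
  cpi <- unlist(g$cpi_by_year)
  structure(list(
    parameters = params,
    baseline_prevalence = g$baseline_prevalence,
    horizon_years = as.integer(unlist(g$horizon_years)),
    cpi_by_year = cpi,
    fx_cop_per_usd = g$fx_cop_per_usd,
    psa_iterations = as.integer(g$psa_iterations)
  ), class = "bia_params")
}

#' Write a parameter set back to YAML
#'
#' Inverse of [load_parameters()]; a load/write/load round trip is
#' lossless.
#'
#' @param ps A `bia_params` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "bia_params"))
  ser_dist <- function(d) {
    if (is.null(d)) return(NULL)
    switch(d$kind,
      beta = list(kind = "beta", a = d$a, b = d$b),
      poisson = list(kind = "poisson", lambda = d$lam),
      gamma = list(kind = "gamma", shape = d$a, scale = d$b,
                   currency = d$currency),
      fixed = list(kind = "fixed", value = d$value))
  }
  pars <- lapply(ps$parameters, function(p) {
    est <- p$estimate
    if (length(est) > 1) est <- as.list(est)
    out <- list(estimate = est, units = p$units)
    d <- ser_dist(p$dist)
    if (!is.null(d)) out$dist <- d
    if (nzchar(p$note)) out$note <- p$note
    out
  })
  doc <- list(
    globals = list(
      baseline_prevalence = ps$baseline_prevalence,
      horizon_years = as.list(as.integer(ps$horizon_years)),
      cpi_by_year = as.list(ps$cpi_by_year),
      fx_cop_per_usd = ps$fx_cop_per_usd,
      psa_iterations = ps$psa_iterations),
    parameters = pars)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Export a parameter set as JSON
#'
#' @param ps A `bia_params` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_parameters_json <- function(ps, path) {
  stopifnot(inherits(ps, "bia_params"))
  doc <- list(
    globals = list(
      baseline_prevalence = ps$baseline_prevalence,
      horizon_years = ps$horizon_years,
      cpi_by_year = as.list(ps$cpi_by_year),
      fx_cop_per_usd = ps$fx_cop_per_usd,
      psa_iterations = ps$psa_iterations),
    parameters = lapply(ps$parameters, function(p) {
      list(estimate = p$estimate, units = p$units,
           dist = if (is.null(p$dist)) NULL else unclass(p$dist),
           note = p$note)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
print.bia_params <- function(x, ...) {
  cat("Budget-impact parameter set:", length(x$parameters),
      "parameters\n")
  cat("  horizon:", paste(x$horizon_years, collapse = ", "),
      "| baseline prevalence:", x$baseline_prevalence,
      "| 1 USD =", x$fx_cop_per_usd, "COP\n")
  invisible(x)
}

#' Point estimate of a named parameter
#'
#' @param ps A `bia_params` object.
#' @param name Canonical parameter name.
#' @param year Optional calendar year, for parameters with per-year
#'   estimates (AMI episode cost).
#' @return Numeric scalar.
#' @export
param_value <- function(ps, name, year = NULL) {
  p <- ps$parameters[[name]]
  if (is.null(p)) stop("unknown parameter '", name, "'")
  est <- p$estimate
  if (length(est) > 1) {
    if (is.null(year)) stop("parameter '", name, "' needs a year")
    est <- unname(est[as.character(year)])[1]
    if (is.null(est) || is.na(est)) {
      stop("parameter '", name, "' has no value for year ", year)
    }
  }
  unname(est)
}

#' Apply a reconciliation policy to every distribution-tagged parameter
#'
#' @inheritParams reconcile
#' @param ps A `bia_params` object.
#' @return The parameter set with every distribution-tagged parameter
#'   passed through [reconcile()].
#' @export
reconcile_parameters <- function(ps,
                                 policy = c("point_estimate",
                                            "distribution_mean",
                                            "rescaled_distribution")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ps, "bia_params"))
  ps$parameters <- lapply(ps$parameters, function(p) {
    if (is.null(p$dist)) p else reconcile(p, policy, ps$fx_cop_per_usd)
  })
  ps
}

# Flat named list of deterministic parameter values used by the engine.
# AMI episode cost stays a per-year vector.
.parameter_values <- function(ps) {
  v <- lapply(ps$parameters, function(p) p$estimate)
  v$fx_cop_per_usd <- ps$fx_cop_per_usd
  v
}

# One PSA draw of every distribution-tagged parameter (COP-scale gamma
# draws are converted to USD); parameters without a distribution keep
# their point estimate.
.sample_parameter_values <- function(ps) {
  v <- .parameter_values(ps)
  for (nm in names(ps$parameters)) {
    d <- ps$parameters[[nm]]$dist
    if (is.null(d) || d$kind == "fixed") next
    draw <- dist_sample(d, 1)
    if (identical(d$currency, "COP")) draw <- draw / ps$fx_cop_per_usd
    v[[nm]] <- draw
  }
  v
}
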