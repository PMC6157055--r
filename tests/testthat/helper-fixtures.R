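# Shared fixtures: the packaged parameter set, a small synthetic
# projection, and the canonical scenario pair with the published 2018
# prevalent-count overrides.

fixture_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_parameters()
    cache
  }
})

fixture_projection <- function(base_total = 33e6, growth = 0.012) {
  generate_population(base_total, growth, 2018:2020)
}

fixture_rules <- function() {
  list(baseline = list(type = "override", counts = c("2018" = 8675154)),
       new = list(type = "override", counts = c("2018" = 13271577)))
}

fixture_scenarios <- function(ps = fixture_params()) {
  rules <- fixture_rules()
  list(baseline = baseline_scenario(ps, rules$baseline),
       new = new_scenario(ps, rules$new, rules$baseline))
}

# Parameter set whose distributions are all removed, so PSA draws
# degenerate to the point estimates.
degenerate_params <- function(ps = fixture_params()) {
  ps$parameters <- lapply(ps$parameters, function(p) {
    p$dist <- NULL
    p
  })
  ps
}
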