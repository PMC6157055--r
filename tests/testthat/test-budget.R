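test_that("a zero-prevalence scenario yields all-zero counts and costs", {
  ps <- fixture_params()
  proj <- fixture_projection()
  sc <- baseline_scenario(ps, list(type = "fixed_rate", rate = 0))
  run <- run_scenario(sc, ps, proj)
  expect_true(all(run$states$n_hypertensive == 0))
  expect_true(all(run$costs$total_usd == 0))
  expect_true(all(unlist(run$events[, c("ami", "stroke", "hf",
                                        "cvdeath")]) == 0))
})

test_that("scenario runs are deterministic", {
  ps <- fixture_params()
  proj <- fixture_projection()
  sc <- fixture_scenarios(ps)
  r1 <- run_scenario(sc$new, ps, proj)
  r2 <- run_scenario(sc$new, ps, proj)
  expect_identical(r1$costs, r2$costs)
  expect_identical(r1$events, r2$events)
})

test_that("a fixture run matches an independent year-by-year recomputation", {
  # spreadsheet-style oracle over the three-year chain, written out with
  # explicit arithmetic and no package internals
  ps <- fixture_params()
  proj <- generate_population(1e6, 0.01, 2018:2020)
  sb <- baseline_scenario(ps, list(type = "override",
                                   counts = c("2018" = 72000)))
  run <- run_scenario(sb, ps, proj)

  pop <- c(1e6, 1010000, 1020100)
  prevalent <- round(72000 * pop / pop[1])
  hyp <- treated <- untreated <- strokes <- totals <- numeric(3)
  carry <- 0
  for (i in 1:3) {
    hyp[i] <- prevalent[i] + carry
    treated[i] <- round(hyp[i] * 0.52 * 0.45)
    untreated[i] <- hyp[i] - treated[i]
    ami <- treated[i] * 0.0078 + untreated[i] * 0.047
    strokes[i] <- treated[i] * 0.0047 + untreated[i] * 0.104
    hf <- treated[i] * 0.0067 + untreated[i] * 0.0396
    deaths <- round(treated[i] * 0.0043 + untreated[i] * 0.0043)
    totals[i] <- treated[i] * 1.8 * 0.00556 * 365 +
      hyp[i] * 0.61 * 57.91 +
      ami * c(2938, 3235, 2934)[i] + strokes[i] * 3430 +
      hf * (2.2 * 1990 + 1131)
    carry <- treated[i] - round(deaths * treated[i] / hyp[i])
  }
  expect_equal(run$states$n_hypertensive, hyp)
  expect_equal(run$states$n_treated, treated)
  expect_equal(run$events$stroke, strokes)
  expect_equal(run$costs$total_usd, totals)
})

test_that("identical scenario specs give identical runs and zero impact", {
  ps <- fixture_params()
  proj <- fixture_projection()
  rule <- list(type = "override", counts = c("2018" = 8675154))
  s1 <- baseline_scenario(ps, rule)
  s2 <- baseline_scenario(ps, rule)
  s2$name <- "clone"
  r1 <- run_scenario(s1, ps, proj)
  r2 <- run_scenario(s2, ps, proj)
  bi <- budget_impact(r1, r2)
  expect_equal(bi$by_year$difference_usd, rep(0, 3))
  expect_equal(bi$total_difference, 0)
})

test_that("budget impact differences are exact and sign-conventioned", {
  ps <- fixture_params()
  proj <- fixture_projection()
  sc <- fixture_scenarios(ps)
  rb <- run_scenario(sc$baseline, ps, proj)
  rn <- run_scenario(sc$new, ps, proj)
  bi <- budget_impact(rb, rn)
  expect_equal(bi$by_year$difference_usd,
               rn$costs$total_usd - rb$costs$total_usd)
  # medication + diagnostics rise under the wider, intensive guideline
  md <- function(r) r$costs$medication_usd + r$costs$diagnostics_usd
  expect_true(all(md(rn) > md(rb)))
  # real-terms horizon total equals the sum of deflated annual totals
  bi_real <- budget_impact(rb, rn, real_terms = TRUE,
                           cpi_by_year = ps$cpi_by_year)
  oracle <- sum(mapply(deflate, rn$costs$total_usd, rn$costs$year,
                       MoreArgs = list(cpi_by_year = ps$cpi_by_year))) -
    sum(mapply(deflate, rb$costs$total_usd, rb$costs$year,
               MoreArgs = list(cpi_by_year = ps$cpi_by_year)))
  expect_equal(bi_real$total_difference, oracle)
})

test_that("mismatched horizons are rejected", {
  ps <- fixture_params()
  proj <- fixture_projection()
  sc <- fixture_scenarios(ps)
  rb <- run_scenario(sc$baseline, ps, proj)
  ps2 <- ps
  ps2$horizon_years <- 2018:2019
  rn <- run_scenario(sc$new, ps2, proj)
  expect_error(budget_impact(rb, rn), "different years")
})

test_that("a degenerate PSA reproduces the deterministic run exactly", {
  ps <- degenerate_params()
  proj <- fixture_projection()
  sc <- fixture_scenarios(ps)
  rb <- run_scenario(sc$baseline, ps, proj)
  rn <- run_scenario(sc$new, ps, proj)
  det_diff <- rn$costs$total_usd - rb$costs$total_usd
  psa <- run_psa(ps, sc, proj, n_iter = 5, seed = 42)
  for (j in 1:5) {
    expect_equal(unlist(psa$draws[j, 1:3], use.names = FALSE), det_diff)
  }
  expect_true(all(psa$fraction_saving %in% c(0, 1)))
})

test_that("the PSA is reproducible for a fixed root seed", {
  ps <- fixture_params()
  proj <- fixture_projection()
  sc <- fixture_scenarios(ps)
  p1 <- run_psa(ps, sc, proj, n_iter = 40, seed = 11)
  p2 <- run_psa(ps, sc, proj, n_iter = 40, seed = 11)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$fraction_saving, p2$fraction_saving)
  p3 <- run_psa(ps, sc, proj, n_iter = 40, seed = 12)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("raising untreated event probabilities raises untreated-pool cost", {
  # single-scenario monotonicity: more avoidable events in the untreated
  # pool can only increase that scenario's complication bill
  ps <- fixture_params()
  proj <- fixture_projection()
  sc <- fixture_scenarios(ps)
  bump <- ps
  for (nm in c("p_ami_untreated", "p_stroke_untreated",
               "p_hf_untreated")) {
    bump$parameters[[nm]]$estimate <-
      1.2 * bump$parameters[[nm]]$estimate
  }
  base_run <- run_scenario(sc$baseline, ps, proj)
  bump_run <- run_scenario(sc$baseline, bump, proj)
  expect_true(all(bump_run$costs$total_usd >= base_run$costs$total_usd))
  # with equal compartments across scenarios the untreated contribution
  # cancels from the difference, so the saving is weakly unchanged
  shared <- list(type = "override", counts = c("2018" = 1e6))
  one_year <- function(p) {
    p$horizon_years <- 2018L
    p
  }
  s_b <- baseline_scenario(ps, shared)
  s_n <- new_scenario(ps, shared, shared)
  diff_of <- function(p) {
    rb <- run_scenario(s_b, p, proj)
    rn <- run_scenario(s_n, p, proj)
    budget_impact(rb, rn)$total_difference
  }
  expect_lte(diff_of(one_year(bump)), diff_of(one_year(ps)))
})
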