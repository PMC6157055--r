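test_that("expected events follow the compartment arithmetic", {
  ps <- fixture_params()
  probs <- event_probabilities(ps)
  st_treated <- partition_treatment(1000, 0, 1, 1, year = 2018,
                                    scenario = "x")
  # oracle: 1000 * 0.0065 (intensive AMI)
  ev <- expected_events(st_treated, probs, "intensive")
  expect_equal(ev$ami, 6.5)
  # oracle: 1000 * 0.1040 (untreated stroke)
  st_untreated <- partition_treatment(1000, 0, 0, 0, year = 2018,
                                      scenario = "x")
  ev2 <- expected_events(st_untreated, probs, "standard")
  expect_equal(ev2$stroke, 104)
  # zero probabilities give zero counts
  zero <- list(standard = c(ami = 0, stroke = 0, hf = 0, cvdeath = 0),
               intensive = c(ami = 0, stroke = 0, hf = 0, cvdeath = 0),
               untreated = c(ami = 0, stroke = 0, hf = 0, cvdeath = 0))
  ev3 <- expected_events(st_treated, zero, "standard")
  expect_equal(unlist(ev3[, c("ami", "stroke", "hf", "cvdeath")]),
               c(ami = 0, stroke = 0, hf = 0, cvdeath = 0))
})

test_that("expected events are linear in compartment sizes", {
  ps <- fixture_params()
  probs <- event_probabilities(ps)
  st1 <- partition_treatment(250000, 50000, 0.52, 0.45, 0.2,
                             year = 2018, scenario = "x")
  st2 <- st1
  st2$n_treated <- 2 * st1$n_treated
  st2$n_untreated <- 2 * st1$n_untreated
  ev1 <- expected_events(st1, probs, "standard")
  ev2 <- expected_events(st2, probs, "standard")
  for (o in c("ami", "stroke", "hf", "cvdeath")) {
    expect_equal(ev2[[o]], 2 * ev1[[o]])
  }
})

test_that("intensive control never exceeds standard with equal compartments", {
  ps <- fixture_params()
  probs <- event_probabilities(ps)
  st <- partition_treatment(5e6, 0, 0.52, 0.45, year = 2018,
                            scenario = "x")
  ev_std <- expected_events(st, probs, "standard")
  ev_int <- expected_events(st, probs, "intensive")
  for (o in c("ami", "stroke", "hf", "cvdeath")) {
    expect_lte(ev_int[[o]], ev_std[[o]])
  }
})

test_that("the untreated cardiovascular-death fallback is configurable", {
  ps <- fixture_params()
  expect_equal(event_probabilities(ps)$untreated[["cvdeath"]], 0.0043)
  expect_equal(event_probabilities(ps, "zero")$untreated[["cvdeath"]], 0)
})

test_that("hazard ratios follow the cumulative-incidence closed form", {
  ps <- fixture_params()
  probs <- event_probabilities(ps)
  st <- partition_treatment(10000, 0, 0.52, 0.45, year = 2018,
                            scenario = "x")
  ev <- expected_events(st, probs, "standard")
  # an arm against itself is exactly 1 for all outcomes
  expect_equal(unname(hazard_ratio(ev, 10000, ev, 10000)),
               rep(1, 4))
  # oracle: ln(1 - 0.0041) / ln(1 - 0.0047) (stroke, intensive vs standard)
  hr <- hazard_ratio(c(ami = 65, stroke = 41, hf = 41, cvdeath = 25),
                     10000,
                     c(ami = 78, stroke = 47, hf = 67, cvdeath = 43),
                     10000)
  expect_equal(hr[["stroke"]], log(1 - 0.0041) / log(1 - 0.0047))
  expect_equal(hr[["stroke"]], 0.872, tolerance = 1e-3)
  # zero rate in the numerator arm gives 0; in the denominator, NA
  hr0 <- hazard_ratio(c(ami = 0, stroke = 0, hf = 0, cvdeath = 0), 100,
                      c(ami = 1, stroke = 1, hf = 1, cvdeath = 0), 100)
  expect_equal(hr0[["ami"]], 0)
  expect_true(is.na(hr0[["cvdeath"]]))
  expect_error(hazard_ratio(c(ami = 200, stroke = 0, hf = 0,
                              cvdeath = 0), 100,
                            c(ami = 1, stroke = 1, hf = 1,
                              cvdeath = 1), 100),
               "exceed")
})

test_that("annualization inverts cumulative trial probabilities", {
  expect_equal(annualize_probability(0, 500, 3.26), 0)
  expect_equal(annualize_probability(500, 500, 1), 1)
  # oracle: 1 - (1 - 116/4678)^(1/3.26); close to the table's 0.0078
  expect_equal(annualize_probability(116, 4678, 3.26),
               1 - (1 - 116 / 4678)^(1 / 3.26))
  expect_equal(annualize_probability(116, 4678, 3.26), 0.0077,
               tolerance = 0.01)
  expect_error(annualize_probability(600, 500, 3.26), "exceed")
})
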