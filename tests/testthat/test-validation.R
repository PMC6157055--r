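test_that("smoothing a constant series returns it with a zero-width CI", {
  for (alpha in c(0.1, 0.5, 1)) {
    fc <- ses_forecast(c(500, 500, 500), alpha = alpha, horizon = 2)
    expect_equal(fc$forecast$forecast, c(500, 500))
    expect_equal(fc$forecast$ci_low, fc$forecast$ci_high)
  }
})

test_that("alpha = 1 forecasts the last observation", {
  fc <- ses_forecast(c(120, 90, 143, 171), alpha = 1, horizon = 3)
  expect_equal(unique(fc$forecast$forecast), 171)
})

test_that("the recursion matches a hand-unrolled series", {
  # oracle: explicit 4-step recursion at alpha = 0.1
  # S1 = 100; S2 = .1*110 + .9*100 = 101; S3 = .1*120 + .9*101 = 102.9;
  # S4 = .1*130 + .9*102.9 = 105.61
  fc <- ses_forecast(c(100, 110, 120, 130), alpha = 0.1, horizon = 2)
  expect_equal(fc$smoothed, c(100, 101, 102.9, 105.61))
  expect_equal(unique(fc$forecast$forecast), 105.61)
  # residuals are y_t - S_{t-1}: 10, 19, 27.1
  sd_resid <- sd(c(10, 19, 27.1))
  expect_equal(fc$sigma, sd_resid)
  expect_equal(fc$forecast$ci_high, rep(105.61 + 1.96 * sd_resid, 2))
  expect_equal(fc$forecast$ci_low, rep(105.61 - 1.96 * sd_resid, 2))
})

test_that("the level agrees with HoltWinters at a fixed alpha", {
  h <- generate_event_history("I64", 800, 25, 40, n_years = 10, seed = 3)
  fc <- ses_forecast(h, alpha = 0.1)
  hw <- stats::HoltWinters(stats::ts(h$count), alpha = 0.1,
                           beta = FALSE, gamma = FALSE)
  expect_equal(unique(fc$forecast$forecast), unname(stats::coef(hw)))
})

test_that("forecasts lie between the series extremes", {
  set.seed(17)
  for (i in 1:20) {
    y <- round(runif(8, 100, 1000))
    alpha <- runif(1, 0.05, 1)
    fc <- ses_forecast(y, alpha = alpha)
    f <- fc$forecast$forecast[1]
    expect_gte(f, min(y))
    expect_lte(f, max(y))
  }
})

test_that("short series are rejected", {
  expect_error(ses_forecast(c(1, 2)), "at least 3")
  expect_error(ses_forecast(c(1, 2, 3), alpha = 0), "alpha")
})

test_that("containment uses a closed interval and is monotone in width", {
  fc <- ses_forecast(c(100, 110, 120, 130), alpha = 0.1, horizon = 3)
  f <- fc$forecast$forecast[1]
  expect_true(all(check_event_containment(rep(f, 3), fc)))
  above <- rep(fc$forecast$ci_high[1] + 1, 3)
  expect_false(any(check_event_containment(above, fc)))
  # boundary values count as contained
  expect_true(all(check_event_containment(rep(fc$forecast$ci_high[1], 3),
                                          fc)))
  # widening the interval never loses a contained point
  wide <- fc
  wide$forecast$ci_low <- fc$forecast$ci_low - 50
  wide$forecast$ci_high <- fc$forecast$ci_high + 50
  for (p in list(rep(f, 3), above, rep(0, 3))) {
    narrow_in <- check_event_containment(p, fc)
    wide_in <- check_event_containment(p, wide)
    expect_true(all(wide_in | !narrow_in))
  }
})

test_that("hazard-ratio checks honour reference intervals and gaps", {
  hrs <- c(ami = 1.0, stroke = 0.4, hf = NA_real_, cvdeath = 0.9)
  refs <- list(ami = c(0.5, 2.0), stroke = c(0.5, 2.0),
               hf = c(0.5, 2.0))
  chk <- check_hazard_ratios(hrs, refs)
  expect_true(chk[["ami"]])
  expect_false(chk[["stroke"]])
  expect_true(is.na(chk[["hf"]]))      # undefined model ratio
  expect_true(is.na(chk[["cvdeath"]])) # no reference supplied
})

test_that("validation reports assemble forecasts, containment and HRs", {
  ps <- fixture_params()
  proj <- fixture_projection()
  sc <- fixture_scenarios(ps)
  rb <- run_scenario(sc$baseline, ps, proj)
  rn <- run_scenario(sc$new, ps, proj)
  histories <- list(
    generate_event_history("I219", 40000, 500, 800, n_years = 8,
                           seed = 21),
    generate_event_history("I509", 46000, 400, 900, n_years = 8,
                           seed = 22),
    generate_event_history("I64", 27000, 300, 700, n_years = 8,
                           seed = 23))
  rep <- validation_report(rb, rn, histories, alpha = 0.1,
                           reference_cis = list(ami = c(0.01, 2),
                                                stroke = c(0.01, 2),
                                                hf = c(0.01, 2)))
  expect_setequal(names(rep$outcomes), c("ami", "hf", "stroke"))
  expect_length(rep$outcomes$ami$contained_baseline, 3)
  expect_true(all(is.finite(rep$hazard_ratios)))
  # reported HRs are the mean of the per-year cumulative-incidence HRs
  hr1 <- hazard_ratio(rn$events[1, ], rn$states$n_hypertensive[1],
                      rb$events[1, ], rb$states$n_hypertensive[1])
  hr3 <- hazard_ratio(rn$events[3, ], rn$states$n_hypertensive[3],
                      rb$events[3, ], rb$states$n_hypertensive[3])
  expect_gte(rep$hazard_ratios[["ami"]], min(hr1[["ami"]], hr3[["ami"]]))
  expect_lte(rep$hazard_ratios[["ami"]], max(hr1[["ami"]], hr3[["ami"]]))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, tmp)
  doc <- jsonlite::read_json(tmp)
  expect_equal(doc$alpha, 0.1)
  expect_named(doc$outcomes, c("ami", "hf", "stroke"),
               ignore.order = TRUE)
})
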