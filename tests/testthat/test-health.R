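test_that("relative risks convert to log-linear slopes", {
  c1 <- crf_from_rr(1.04, 1.013, 1.067, 10, "o3", "respiratory")
  expect_equal(c1$beta, log(1.04) / 10)
  expect_equal(c1$beta, 3.922e-3, tolerance = 1e-3)
  expect_equal(c1$beta_se, log(1.067 / 1.013) / (2 * 1.96 * 10))
  expect_equal(c1$beta_se, 1.325e-3, tolerance = 1e-3)

  c2 <- crf_from_rr(1.13, 1.10, 1.16, 10, "pm25", "cardiopulmonary")
  expect_equal(c2$beta, 1.222e-2, tolerance = 1e-3)

  null <- crf_from_rr(1, 1, 1, 10, "pm25", "all_cause")
  expect_equal(null$beta, 0)
  expect_equal(null$beta_se, 0)

  expect_error(crf_from_rr(1.04, 1.05, 1.067, 10, "o3", "respiratory"),
               "rr_lo")
  expect_error(crf_from_rr(1.04, 1.013, 1.02, 10, "o3", "respiratory"),
               "rr_")
})

test_that("direct slopes pass through and agree with the RR route", {
  d <- crf_direct(0.00432, 0.00121, "o3", "respiratory")
  expect_equal(d$beta, 0.00432)
  expect_equal(d$beta_se, 0.00121)
  expect_error(crf_direct(0.004, -0.001, "o3", "respiratory"), ">= 0")
  expect_equal(crf_direct(log(1.04) / 10, 0, "o3", "respiratory")$beta,
               crf_from_rr(1.04, 1.013, 1.067, 10, "o3", "respiratory")$beta)
})

test_that("attributable fraction follows 1 - exp(-beta dX) with its bounds", {
  g <- make_grid(2, 4)
  dx10 <- delta_exposure(as_pm_surface(const_field(10, g)),
                         as_pm_surface(const_field(0, g)))
  crf <- crf_from_rr(1.04, 1.013, 1.067, 10, "pm25", "cardiopulmonary")
  af <- attributable_fraction(crf, dx10)
  expect_equal(af$values[1, 1], 1 - 1 / 1.04, tolerance = 1e-14)
  expect_equal(af$values[1, 1], (1.04 - 1) / 1.04, tolerance = 1e-14)

  null <- crf_direct(0, 0, "pm25", "cardiopulmonary")
  expect_true(all(attributable_fraction(null, dx10)$values == 0))

  # monotone in dX, bounded in [0, 1)
  prev <- -1
  for (d in c(0, 1, 10, 100, 1e3)) {
    dd <- delta_exposure(as_pm_surface(const_field(d, g)),
                         as_pm_surface(const_field(0, g)))
    a <- attributable_fraction(crf, dd)$values[1, 1]
    expect_gte(a, 0); expect_lt(a, 1)
    expect_gt(a, prev - 1e-15)
    prev <- a
  }

  o3crf <- crf_from_rr(1.04, 1.013, 1.067, 10, "o3", "respiratory")
  expect_error(attributable_fraction(o3crf, dx10), "unit mismatch")
})

test_that("RR-to-AF consistency holds at the source increment", {
  for (rr in c(1.04, 1.06, 1.13, 1.14, 1.29)) {
    crf <- crf_from_rr(rr, rr, rr, 10, "pm25", "cardiopulmonary")
    g <- make_grid(2, 4)
    dx <- delta_exposure(as_pm_surface(const_field(10, g)),
                         as_pm_surface(const_field(0, g)))
    expect_equal(attributable_fraction(crf, dx)$values[1, 1], (rr - 1) / rr,
                 tolerance = 1e-14)
  }
})

test_that("excess mortality and YLL are cell-wise products", {
  g <- make_grid(2, 4)
  mort <- excess_mortality(const_field(0.1, g), const_field(0.01, g),
                           const_field(1e6, g))
  expect_equal(mort$values[1, 1], 1000)

  set.seed(13)
  af <- gridded_field(g, matrix(runif(8, 0, 0.5), 2, 4))
  y0 <- gridded_field(g, matrix(runif(8, 0, 0.02), 2, 4))
  pop <- gridded_field(g, matrix(runif(8, 0, 1e6), 2, 4))
  m <- excess_mortality(af, y0, pop)
  expect_equal(m$values, af$values * y0$values * pop$values,
               tolerance = 1e-14)

  yll <- years_of_life_lost(m, const_field(7.89, g))
  expect_equal(yll$values, m$values * 7.89, tolerance = 1e-14)
  expect_equal(years_of_life_lost(m, const_field(1, g))$values, m$values)
})

test_that("scenario burdens are linear in population and baseline rates", {
  w <- test_world()
  crfs <- default_crfs()
  base <- run_scenario(w, crfs)

  w2 <- w
  w2$population <- gridded_field(w$grid, 2 * w$population$values,
                                 units = "persons")
  doubled <- run_scenario(w2, crfs)
  for (pn in names(base$burdens))
    expect_equal(doubled$burdens[[pn]]$mort$values,
                 2 * base$burdens[[pn]]$mort$values, tolerance = 1e-12)

  w3 <- w
  w3$tables$countries$rate <- w$tables$countries$rate * 0.5
  w3$tables$regions$rate <- w$tables$regions$rate * 0.5
  halved <- run_scenario(w3, crfs)
  for (pn in names(base$burdens))
    expect_equal(halved$burdens[[pn]]$mort$values,
                 0.5 * base$burdens[[pn]]$mort$values, tolerance = 1e-12)
})

test_that("an inactive low threshold leaves burdens unchanged", {
  w <- test_world()
  crfs <- default_crfs()
  exp0 <- scenario_exposures(w)
  # lct below every preindustrial value and hct above every present value
  lo <- min(vapply(exp0, function(e) min(e$preindustrial$values$values),
                   numeric(1)))
  hi <- max(vapply(exp0, function(e) max(e$present$values$values),
                   numeric(1)))
  base <- run_scenario(w, crfs)
  inert <- run_scenario(w, crfs, threshold_policy(lct = lo * 0.5,
                                                  hct = hi * 2))
  for (pn in names(base$burdens))
    expect_equal(inert$burdens[[pn]]$mort$values,
                 base$burdens[[pn]]$mort$values, tolerance = 1e-12)
})

test_that("thresholds can only reduce burdens, cell-wise and in aggregate", {
  w <- test_world()
  crfs <- default_crfs()
  base <- run_scenario(w, crfs)
  lct <- run_scenario(w, crfs, list(o3 = threshold_policy(lct = 33.3),
                                    pm25 = threshold_policy(lct = 5.8)))
  hct <- run_scenario(w, crfs, list(o3 = threshold_policy(),
                                    pm25 = threshold_policy(hct = 30)))
  for (pn in names(base$burdens)) {
    expect_true(all(lct$burdens[[pn]]$mort$values <=
                      base$burdens[[pn]]$mort$values + 1e-12))
    expect_true(all(hct$burdens[[pn]]$mort$values <=
                      base$burdens[[pn]]$mort$values + 1e-12))
    expect_lte(sum(lct$burdens[[pn]]$mort$values),
               sum(base$burdens[[pn]]$mort$values))
  }
  # the LCT bites on this world
  expect_lt(sum(lct$burdens$o3_respiratory$mort$values),
            sum(base$burdens$o3_respiratory$mort$values))
})

test_that("small-slope burdens match the first-order expansion", {
  w <- test_world()
  tiny <- crf_direct(1e-5, 0, "pm25", "cardiopulmonary")
  res <- run_scenario(w, list(tiny))
  exp0 <- scenario_exposures(w)
  dx <- delta_exposure(exp0$pm25$present, exp0$pm25$preindustrial)
  y0 <- rate_surface(w$tables, w$wmap, "cardiopulmonary", w$grid)
  adults <- adult_population(w$population, w$tables, w$regions)
  linear <- sum(y0$values * tiny$beta * dx$values$values * adults$values)
  expect_equal(sum(res$burdens$pm25_cardiopulmonary$mort$values), linear,
               tolerance = 0.01)
})

test_that("cross-pollutant summation is explicit and flagged", {
  w <- test_world()
  res <- run_scenario(w, default_crfs())
  total <- sum_burdens(res$burdens)
  expect_true(total$double_counting_warning)
  expect_equal(total$mort$values,
               Reduce(`+`, lapply(res$burdens, function(b) b$mort$values)))
  pm_only <- sum_burdens(res$burdens[c("pm25_cardiopulmonary",
                                       "pm25_lung_cancer")])
  expect_false(pm_only$double_counting_warning)
})
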