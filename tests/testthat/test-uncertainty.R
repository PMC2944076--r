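test_that("slope draws are seeded, truncated normals with the right moments", {
  crf <- crf_direct(1, 0.1, "pm25", "cardiopulmonary")
  cfg <- mc_config(n_draws = 1e5, seed = 11)
  b <- draw_betas(crf, cfg)
  expect_identical(b, draw_betas(crf, cfg))
  # truncation at 0 is negligible 10 SDs from zero
  se <- 0.1 / sqrt(1e5)
  expect_lt(abs(mean(b) - 1), 3 * se)
  expect_lt(abs(sd(b) - 0.1), 3 * 0.1 / sqrt(2 * 1e5))

  degenerate <- draw_betas(crf_direct(0.5, 0, "o3", "respiratory"),
                           mc_config(n_draws = 100, seed = 1))
  expect_true(all(degenerate == 0.5))

  wide <- draw_betas(crf_direct(0.1, 10, "o3", "respiratory"),
                     mc_config(n_draws = 1000, seed = 2))
  expect_true(all(wide >= 0))  # negative slope draws truncated
})

test_that("present-day perturbation modes behave as constructed", {
  w <- test_world()
  present <- scenario_exposures(w)$pm25$present

  ident <- perturb_present(present, mc_config(conc_sd_fraction = 0,
                                              seed = 1), 1)
  expect_identical(ident$values$values, present$values$values)

  corr <- perturb_present(present, mc_config(conc_mode = "correlated",
                                             seed = 3), 2)
  ratio <- corr$values$values / present$values$values
  expect_lt(diff(range(ratio)), 1e-12)  # one factor for every cell

  cfg_ind <- mc_config(conc_mode = "independent", seed = 3)
  ind <- perturb_present(present, cfg_ind, 2)
  f <- ind$values$values / present$values$values
  expect_equal(sd(as.vector(f)), 0.25, tolerance = 0.05)
  # different draws use different factors; same draw reproduces
  expect_identical(perturb_present(present, cfg_ind, 2)$values$values,
                   ind$values$values)
  expect_false(identical(perturb_present(present, cfg_ind, 3)$values$values,
                         ind$values$values))
})

test_that("zero uncertainty collapses the Monte Carlo to the point estimate", {
  w <- test_world()
  crfs <- list(crf_direct(log(1.04) / 10, 0, "o3", "respiratory"),
               crf_direct(log(1.13) / 10, 0, "pm25", "cardiopulmonary"))
  mc <- mc_burden(w, crfs, cfg = mc_config(n_draws = 10,
                                           conc_sd_fraction = 0, seed = 5))
  for (pn in names(mc$pairs)) {
    reg <- mc$pairs[[pn]]$regional
    expect_equal(reg$mort_mean, reg$mort_point, tolerance = 1e-14)
    expect_true(all(reg$mort_sd == 0))
    expect_true(all(mc$pairs[[pn]]$mort_sd$values == 0))
  }
})

test_that("identical configurations reproduce bit-identical Monte Carlo results", {
  w <- test_world()
  crfs <- default_crfs()
  cfg <- mc_config(n_draws = 40, seed = 17)
  m1 <- mc_burden(w, crfs, cfg = cfg)
  m2 <- mc_burden(w, crfs, cfg = cfg)
  for (pn in names(m1$pairs)) {
    expect_identical(m1$pairs[[pn]]$regional, m2$pairs[[pn]]$regional)
    expect_identical(m1$pairs[[pn]]$mort_sd$values,
                     m2$pairs[[pn]]$mort_sd$values)
  }
  m3 <- mc_burden(w, crfs, cfg = mc_config(n_draws = 40, seed = 18))
  expect_false(identical(m1$pairs[[1]]$regional, m3$pairs[[1]]$regional))
})

test_that("draw count below two is rejected", {
  expect_error(mc_config(n_draws = 1), "n_draws")
})

test_that("uncertainty components each contribute less than their combination", {
  w <- test_world()
  crf <- crf_from_rr(1.13, 1.10, 1.16, 10, "pm25", "cardiopulmonary")
  world_sd <- function(cfg) {
    mc <- mc_burden(w, list(crf), cfg = cfg)
    reg <- mc$pairs[[1]]$regional
    reg$mort_sd[reg$region == "World"]
  }
  sd_beta <- world_sd(mc_config(n_draws = 200, conc_sd_fraction = 0,
                                seed = 21))
  sd_conc <- world_sd(mc_config(n_draws = 200, conc_sd_fraction = 0.25,
                                seed = 21))
  # conc-only: remove slope uncertainty
  crf0 <- crf_direct(crf$beta, 0, "pm25", "cardiopulmonary")
  mc_conc <- mc_burden(w, list(crf0),
                       cfg = mc_config(n_draws = 200, seed = 21))
  reg <- mc_conc$pairs[[1]]$regional
  sd_conc_only <- reg$mort_sd[reg$region == "World"]

  expect_lte(sd_beta, sd_conc * 1.05)
  expect_lte(sd_conc_only, sd_conc * 1.05)
  expect_gt(sd_conc, sd_beta)
})

test_that("correlated concentration errors give larger aggregate SDs than independent", {
  w <- test_world()
  crf0 <- crf_direct(log(1.13) / 10, 0, "pm25", "cardiopulmonary")
  sd_of <- function(mode) {
    mc <- mc_burden(w, list(crf0),
                    cfg = mc_config(n_draws = 200, conc_mode = mode,
                                    seed = 23))
    reg <- mc$pairs[[1]]$regional
    reg$mort_sd[reg$region == "World"]
  }
  expect_gt(sd_of("correlated"), sd_of("independent"))
})

test_that("Monte Carlo SD matches the delta method in the small-slope regime", {
  w <- test_world()
  beta <- 1e-5
  crf <- crf_direct(beta, 0.3 * beta, "pm25", "cardiopulmonary")
  mc <- mc_burden(w, list(crf),
                  cfg = mc_config(n_draws = 500, conc_sd_fraction = 0,
                                  seed = 29))
  reg <- mc$pairs[[1]]$regional
  world <- reg[reg$region == "World", ]
  # burden ~ linear in beta, so SD/point ~ beta_se/beta
  expect_equal(world$mort_sd / world$mort_point, 0.3, tolerance = 0.1)
  # and the MC mean obeys the CLT bound around the point estimate
  expect_lt(abs(world$mort_mean - world$mort_point),
            3 * world$mort_sd / sqrt(500))
})
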