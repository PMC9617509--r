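study_fixture <- function() {
  cfg <- default_study_config()
  cfg$pk_model <- default_pk_calibration(cfg$agents, cfg$geometry)
  cfg
}

test_that("binding kinetics conserve mass when elimination is off", {
  par <- binding_kinetics_params(k_on = 86.4, kd = 0.0218,
                                 k_el_drug = 1e-12, k_el_vegf = 1e-12,
                                 k_el_complex = 1e-12)
  tr <- simulate_binding_kinetics(10, 5, par, duration = 2, mode = "kinetic")
  expect_lt(max(abs((tr$drug_free + tr$complex) / 10 - 1)), 1e-6)
  expect_lt(max(abs((tr$vegf_free + tr$complex) / 5 - 1)), 1e-6)
  expect_true(all(tr$drug_free >= 0 & tr$vegf_free >= 0 & tr$complex >= 0))
})

test_that("without drug, VEGF decays by its closed-form exponential", {
  par <- binding_kinetics_params(k_on = 86.4, kd = 0.0218,
                                 k_el_drug = 0.2, k_el_vegf = 0.35,
                                 k_el_complex = 0.15)
  for (mode in c("kinetic", "equilibrium")) {
    tr <- simulate_binding_kinetics(0, 17.4, par, duration = 2, mode = mode)
    expect_equal(tr$vegf_free, 17.4 * exp(-0.35 * tr$time),
                 tolerance = 1e-6, label = mode)
  }
})

test_that("quasi-equilibrium mode matches the full ODE oracle", {
  cfg <- study_fixture()
  ag <- cfg$agents$ranibizumab
  par <- default_binding_params(ag, cfg$pk_model, cfg$design)
  # diffusion-limited binding: free-VEGF AUC from the algebraic partition
  # agrees with the stiff ODE within 1% wherever free VEGF is appreciable
  for (d0 in c(2, 5, 11, 16)) {
    eq <- percent_free_vegf(ag, cfg$geometry, cfg$design, par, d0)
    ki <- percent_free_vegf(ag, cfg$geometry, cfg$design, par, d0,
                            mode = "kinetic")
    expect_lt(abs(eq$auc_free / ki$auc_free - 1), 0.01,
              label = sprintf("drug0 = %g nM", d0))
  }
})

test_that("percent free VEGF has the vehicle and capture limits", {
  cfg <- study_fixture()
  ag <- cfg$agents$aflibercept
  par <- default_binding_params(ag, cfg$pk_model, cfg$design)
  # vehicle definition: no drug leaves 100% free
  pf0 <- percent_free_vegf(ag, cfg$geometry, cfg$design, par, 0)
  expect_equal(pf0$percent_free, 100, tolerance = 1e-9)
  # vast site excess at sub-pM affinity captures essentially everything
  pf_hi <- percent_free_vegf(ag, cfg$geometry, cfg$design, par, 5000)
  expect_lt(pf_hi$percent_free, 0.1)
  # 10-fold site excess with kd far below vegf0: well under 10% free
  vegf0 <- mass_to_nM(cfg$design$vegf_dose_mass / 1000,
                      cfg$design$vegf_molecular_weight,
                      cfg$geometry$vitreous_volume) * ag$sites_per_vegf
  pf10 <- percent_free_vegf(ag, cfg$geometry, cfg$design, par, 10 * vegf0)
  expect_lt(pf10$percent_free, 10)
})

test_that("percent free VEGF is monotone in drug and in kd", {
  cfg <- study_fixture()
  ag <- cfg$agents$ranibizumab
  par <- default_binding_params(ag, cfg$pk_model, cfg$design)
  pf <- vapply(c(0, 2, 5, 10, 20, 40), function(d0)
    percent_free_vegf(ag, cfg$geometry, cfg$design, par, d0)$percent_free,
    numeric(1))
  expect_true(all(diff(pf) < 0))
  pf_kd <- vapply(c(0.001, 0.1, 1, 10), function(kd) {
    p <- binding_kinetics_params(par$k_on, kd, par$k_el_drug,
                                 par$k_el_vegf, par$k_el_complex)
    percent_free_vegf(ag, cfg$geometry, cfg$design, p, 15)$percent_free
  }, numeric(1))
  expect_true(all(diff(pf_kd) > 0))
})

test_that("protection is lost latest for aflibercept, earliest for ranibizumab", {
  cfg <- study_fixture()
  truth <- leakage_logistic(70, 24 / log(4))
  cross <- vapply(cfg$agents, function(ag) {
    tc <- protection_timecourse(ag, cfg$geometry, cfg$design, truth,
                                cfg$pk_model,
                                days = seq(5, 70, by = 1))
    tc$challenge_day[which(tc$probability >= 0.5)[1]]
  }, numeric(1))
  expect_gt(cross[["aflibercept"]], cross[["brolucizumab"]])
  expect_gt(cross[["brolucizumab"]], cross[["ranibizumab"]])
  # day-0 challenge at full dose: all agents protect almost completely
  for (ag in cfg$agents) {
    tc0 <- protection_timecourse(ag, cfg$geometry, cfg$design, truth,
                                 cfg$pk_model, days = 0)
    expect_lt(tc0$probability, 0.2)
  }
  # the ordering survives +/-25% perturbation of every half-life
  for (mult in c(0.75, 1.25)) {
    cr <- vapply(cfg$agents, function(ag) {
      tc <- protection_timecourse(ag, cfg$geometry, cfg$design, truth,
                                  cfg$pk_model,
                                  t_half = mult * ag$vitreal_half_life,
                                  days = seq(5, 90, by = 2))
      tc$challenge_day[which(tc$probability >= 0.5)[1]]
    }, numeric(1))
    expect_true(cr[["aflibercept"]] > cr[["brolucizumab"]] &&
                  cr[["brolucizumab"]] > cr[["ranibizumab"]],
                label = sprintf("half-lives x %g", mult))
  }
})

test_that("design window search finds and shrinks windows sensibly", {
  cfg <- study_fixture()
  truth <- leakage_logistic(70, 24 / log(4))
  grid <- seq(5, 70, by = 5)
  w0 <- find_design_window(cfg$agents, cfg$geometry, cfg$design, truth,
                           cfg$pk_model, day_grid = grid, margin = 0)
  expect_false(w0$empty)
  # margin growth can only shrink the window
  w1 <- find_design_window(cfg$agents, cfg$geometry, cfg$design, truth,
                           cfg$pk_model, day_grid = grid, margin = 0.02)
  if (!w1$empty) {
    expect_gte(w1$start_day, w0$start_day)
    expect_lte(w1$end_day, w0$end_day)
  }
  # identical agents cannot be discriminated
  twins <- list(cfg$agents$ranibizumab, cfg$agents$ranibizumab)
  tw <- find_design_window(twins, cfg$geometry, cfg$design, truth,
                           cfg$pk_model, day_grid = grid)
  expect_true(tw$empty)
})
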