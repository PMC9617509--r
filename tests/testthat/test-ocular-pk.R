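test_that("hydrodynamic radius follows the size-scaling law", {
  expect_equal(hydrodynamic_radius(8 * 40), 2 * hydrodynamic_radius(40))
  expect_equal(hydrodynamic_radius(26) / hydrodynamic_radius(48),
               (26 / 48)^(1 / 3))
  # cube-root arithmetic: 0.5416667^(1/3)
  expect_equal(hydrodynamic_radius(26) / hydrodynamic_radius(48), 0.81517,
               tolerance = 1e-4)
  expect_equal(hydrodynamic_radius(40, prefactor = 2),
               2 * hydrodynamic_radius(40))
  expect_error(hydrodynamic_radius(-1), "molecular_weight")
})

test_that("anterior-route model predicts half-life proportional to radius", {
  geom <- eye_geometry()
  model <- calibrate_anterior_model(geom, anchor_mw = 48,
                                    anchor_half_life = 3.8)
  # anchor reproduces itself
  expect_equal(predict_vitreal_half_life(48, model), 3.8, tolerance = 1e-10)
  # cube-root scaling: 8x the mass doubles radius and half-life
  expect_equal(predict_vitreal_half_life(8 * 48, model), 2 * 3.8,
               tolerance = 1e-8)
  # monotone increasing in molecular weight
  th <- vapply(c(10, 26, 48, 115, 150), predict_vitreal_half_life,
               numeric(1), model)
  expect_true(all(diff(th) > 0))
  # observed ordering of the three agents
  ths <- vapply(default_agents(),
                function(a) predict_vitreal_half_life(a, model), numeric(1))
  expect_gt(ths[["aflibercept"]], ths[["ranibizumab"]])
  expect_gt(ths[["ranibizumab"]], ths[["brolucizumab"]])
})

test_that("infinite aqueous turnover leaves transfer-limited elimination", {
  # with very fast anterior-chamber washout the slow eigenvalue equals the
  # vitreous-to-aqueous transfer rate: one-compartment closed form
  p <- pk_model_params(hydrodynamic_radius = 3,
                       transfer_rate_vit_to_aq = 0.2,
                       aqueous_elimination_rate = 1e6,
                       geometry_factor = 1)
  expect_equal(predict_vitreal_half_life(48, p), log(2) / 0.2,
               tolerance = 1e-9)
  # and a calibration faster than aqueous turnover is rejected
  slow_eye <- eye_geometry(aqueous_outflow = 0.01)
  expect_error(calibrate_anterior_model(slow_eye, 48, 3.8),
               "aqueous turnover")
})

test_that("simulated destructive profiles behave and reproduce under seed", {
  ag <- default_agents()$aflibercept
  geom <- eye_geometry()
  p0 <- simulate_profile(ag, geom, t_half = 5.63, schedule = c(5, 26, 54),
                         n_per_day = 3, noise_cv = 0, lloq = 1e-3)
  c0 <- ag$dose_mass / geom$vitreous_volume
  expect_equal(unique(p0$conc), c0 * 2^(-c(5, 26, 54) / 5.63))
  # lloq above C0 flags every point
  p_flag <- simulate_profile(ag, geom, 5.63, schedule = c(5, 26),
                             n_per_day = 2, noise_cv = 0, lloq = 2 * c0)
  expect_true(all(p_flag$below_lloq))
  # seeded reproducibility
  p1 <- simulate_profile(ag, geom, 5.63, seed = 99)
  p2 <- simulate_profile(ag, geom, 5.63, seed = 99)
  expect_identical(p1, p2)
  p3 <- simulate_profile(ag, geom, 5.63, seed = 100)
  expect_false(identical(p1$conc, p3$conc))
})

test_that("profiles round-trip through the delimited-text reader", {
  spec <- synthetic_study_spec(seed = 8)
  profs <- generate_vitreous_pk_dataset(spec)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_concentration_profiles(profs, tf)
  back <- read_concentration_profiles(tf)
  expect_setequal(names(back), names(profs))
  for (nm in names(profs)) {
    expect_equal(sort(back[[nm]]$conc), sort(profs[[nm]]$conc))
    expect_equal(attr(back[[nm]], "lloq"), attr(profs[[nm]], "lloq"))
    expect_equal(sum(back[[nm]]$below_lloq), sum(profs[[nm]]$below_lloq))
  }
})
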