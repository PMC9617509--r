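test_that("equilibrium free fraction solves the mass balance", {
  # no ligand: everything free
  expect_equal(equilibrium_free_fraction(5e-12, 0, 1e-13), 1)

  # against an independent bisection oracle over a concentration grid
  for (I in c(2.5e-12, 50e-12, 1e-9)) {
    for (L in c(0, 1e-13, I / 2, I, 10 * I)) {
      for (K in c(1.719e-13, 1.3e-12, 2.18e-11)) {
        expect_equal(equilibrium_free_fraction(I, L, K),
                     free_fraction_bisect(I, L, K),
                     tolerance = 1e-9,
                     label = sprintf("I=%g L=%g K=%g", I, L, K))
      }
    }
  }

  # spec anchor point
  expect_equal(equilibrium_free_fraction(100e-12, 50e-12, 1.3e-12),
               0.512, tolerance = 1e-3)

  # weak-binding limit: K >> I, L leaves the inhibitor free
  expect_equal(equilibrium_free_fraction(1e-12, 1e-12, 1e-6), 1,
               tolerance = 1e-3)

  expect_error(equilibrium_free_fraction(-1e-12, 0, 1e-12), "inhibitor")
})

test_that("free fraction is monotone in ligand and in kd", {
  L <- 10^seq(-14, -9, length.out = 30)
  f <- equilibrium_free_fraction(1e-11, L, 1e-12)
  expect_true(all(diff(f) < 0))
  K <- 10^seq(-14, -10, length.out = 30)
  fk <- vapply(K, function(k) equilibrium_free_fraction(1e-11, 1e-11, k),
               numeric(1))
  expect_true(all(diff(fk) > 0))
})

test_that("kinexa signal model has the right limits", {
  cv <- binding_curve(1e-11, 10^seq(-13, -7, length.out = 7), rep(0, 7))
  s <- kinexa_signal(cv, kd = 1e-12, amplitude = 1, background = 0.1)
  # saturation: highest titrant drives signal to background
  expect_equal(s[[7]], 0.1, tolerance = 1e-3)
  # negligible titrant: background + amplitude
  expect_equal(s[[1]], 1.1, tolerance = 2e-2)
  # drift = 0 is exactly the no-drift model
  expect_identical(s, kinexa_signal(cv, 1e-12, 1, 0.1, drift = 0))
})

test_that("global N-curve fit recovers noiseless parameters exactly", {
  ag <- default_agents()$aflibercept
  spec <- synthetic_study_spec(seed = 7, noise_cv_binding = 0)
  curves <- generate_kinexa_dataset(spec, ag)
  fit <- fit_ncurve(curves, conf_level = NA)
  expect_lt(abs(fit$kd / ag$kd_assay - 1), 0.01)
  expect_equal(fit$per_curve_amplitude, rep(1, 6), tolerance = 1e-5)
  expect_equal(fit$per_curve_background, rep(0, 6), tolerance = 1e-6)
  # drift-enabled fit nests the no-drift truth
  fit_d <- fit_ncurve(curves, use_drift = TRUE, conf_level = NA)
  expect_lt(abs(fit_d$kd / ag$kd_assay - 1), 0.01)
})

test_that("flat curves are rejected, not silently fitted", {
  cv <- binding_curve(1e-11, 10^seq(-13, -9, length.out = 6), rep(0.5, 6))
  expect_error(fit_ncurve(list(cv)), "flat|amplitude")
})

test_that("three constant concentrations constrain kd better than one", {
  ag <- default_agents()$aflibercept
  kd3 <- kd1 <- numeric(25)
  for (s in 1:25) {
    spec <- synthetic_study_spec(seed = s)
    curves <- generate_kinexa_dataset(spec, ag)
    kd3[s] <- fit_ncurve(curves, conf_level = NA)$kd
    kd1[s] <- fit_ncurve(curves[1], conf_level = NA)$kd
  }
  expect_lt(stats::sd(log(kd3)), stats::sd(log(kd1)))
})

test_that("profile-likelihood interval behaves and nests across levels", {
  ag <- default_agents()$aflibercept
  spec <- synthetic_study_spec(seed = 3)
  curves <- generate_kinexa_dataset(spec, ag)
  fit <- fit_ncurve(curves, conf_level = NA)
  ci95 <- kd_confidence_interval(fit, curves, level = 0.95)
  ci68 <- kd_confidence_interval(fit, curves, level = 0.68)
  expect_lte(ci95[["low"]], fit$kd)
  expect_gte(ci95[["high"]], fit$kd)
  expect_lte(ci95[["low"]], ci68[["low"]])
  expect_gte(ci95[["high"]], ci68[["high"]])
  # at 2% signal noise the interval spans roughly a factor of a few,
  # commensurate with the assay's reported spread
  width <- ci95[["high"]] / ci95[["low"]]
  expect_gt(width, 1.05)
  expect_lt(width, 50)

  # noiseless data: interval collapses towards the grid resolution
  spec0 <- synthetic_study_spec(seed = 3, noise_cv_binding = 0)
  curves0 <- generate_kinexa_dataset(spec0, ag)
  fit0 <- fit_ncurve(curves0, conf_level = NA)
  ci0 <- kd_confidence_interval(fit0, curves0)
  expect_lt(ci0[["high"]] / ci0[["low"]], 1.5)
})

test_that("binding curves round-trip through delimited text", {
  spec <- synthetic_study_spec(seed = 5)
  curves <- generate_kinexa_dataset(spec, default_agents()$ranibizumab)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_binding_curves(curves, tf)
  back <- read_binding_curves(tf)
  expect_length(back, length(curves))
  ids <- vapply(curves, `[[`, character(1), "replicate_id")
  for (i in seq_along(curves)) {
    expect_equal(back[[ids[[i]]]]$signals, curves[[i]]$signals)
    expect_equal(back[[ids[[i]]]]$titrant_concs, curves[[i]]$titrant_concs)
  }
})
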