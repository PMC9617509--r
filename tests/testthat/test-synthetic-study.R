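test_that("generators are byte-reproducible under a fixed seed", {
  s1 <- synthetic_study_spec(seed = 17)
  s2 <- synthetic_study_spec(seed = 17)
  ag <- s1$agents$brolucizumab
  expect_identical(generate_kinexa_dataset(s1, ag),
                   generate_kinexa_dataset(s2, ag))
  expect_identical(generate_vitreous_pk_dataset(s1),
                   generate_vitreous_pk_dataset(s2))
  expect_identical(generate_leakage_dataset(s1), generate_leakage_dataset(s2))
  # a different seed moves the noise but not the design grid
  s3 <- synthetic_study_spec(seed = 18)
  k1 <- generate_kinexa_dataset(s1, ag)
  k3 <- generate_kinexa_dataset(s3, ag)
  expect_false(identical(k1[[1]]$signals, k3[[1]]$signals))
  expect_identical(k1[[1]]$titrant_concs, k3[[1]]$titrant_concs)
})

test_that("KinExA generator reproduces the assay designs", {
  spec <- synthetic_study_spec(seed = 1)
  curves <- generate_kinexa_dataset(spec, spec$agents$aflibercept)
  # 3 constant concentrations x duplicate
  expect_length(curves, 6)
  consts <- sort(unique(vapply(curves, `[[`, numeric(1), "constant_conc")))
  expect_equal(consts, c(2.5e-12, 5e-12, 50e-12))
  # 3-fold series topping at 1 nM and spanning down to ~50 fM
  tit <- curves[[1]]$titrant_concs
  expect_equal(max(tit), 1e-9)
  expect_lt(min(tit), 60e-15)
  expect_equal(unique(round(tit[-1] / tit[-length(tit)], 6)), 3)
  # ranibizumab uses two constant levels
  curves_r <- generate_kinexa_dataset(spec, spec$agents$ranibizumab)
  expect_length(curves_r, 4)
  # zero noise lands exactly on the model
  spec0 <- synthetic_study_spec(seed = 1, noise_cv_binding = 0)
  c0 <- generate_kinexa_dataset(spec0, spec$agents$aflibercept)[[1]]
  expect_equal(c0$signals, kinexa_signal(c0, spec$agents$aflibercept$kd_assay),
               tolerance = 1e-12)
})

test_that("vitreous PK generator honors cohort sizes and assay LLOQs", {
  spec <- synthetic_study_spec(seed = 2)
  profs <- generate_vitreous_pk_dataset(spec)
  expect_named(profs, c("aflibercept", "brolucizumab", "ranibizumab"))
  p <- profs$aflibercept
  expect_equal(as.vector(table(p$day)),
               rep(spec$animals_per_group, length(spec$pk_sampling_days)))
  expect_equal(attr(p, "lloq"), 6.25e-3)
  expect_equal(attr(profs$brolucizumab, "lloq"), 20e-3)
  expect_equal(attr(profs$ranibizumab, "lloq"), 3e-3)
  expect_equal(p$below_lloq, p$conc < 6.25e-3)
})

test_that("leakage generator matches the cohort design", {
  spec <- synthetic_study_spec(seed = 3)
  d <- generate_leakage_dataset(spec)
  # 3 agents + vehicle, 6 challenge days, 7 animals each
  expect_equal(nrow(d), 4 * 6 * 7)
  expect_setequal(unique(d$agent),
                  c("aflibercept", "brolucizumab", "ranibizumab", "vehicle"))
  counts <- table(d$agent, d$challenge_day)
  expect_true(all(counts == 7))
  # no animal is challenged more than twice
  challenges <- tapply(d$challenge_day, d$animal_id,
                       function(x) length(unique(x)))
  expect_lte(max(challenges), 2)
  # vehicle animals sit at 100% free VEGF by definition
  expect_true(all(d$percent_free[d$agent == "vehicle"] == 100))
  # observation times fall in the 47 +/- 3 h protocol window
  expect_true(all(abs(d$observation_hours - 47) <= 3))
  # scores encode the dichotomization rule
  expect_true(all(d$score %in% c(0L, 1L, 3L)))
})

test_that("the full synthetic study writes three readable datasets", {
  spec <- synthetic_study_spec(seed = 4)
  out <- withr::local_tempdir()
  paths <- write_synthetic_study(spec, out)
  expect_true(all(file.exists(paths)))
  curves <- read_binding_curves(paths[["kinexa"]])
  expect_length(curves, 6 + 6 + 4)
  profs <- read_concentration_profiles(paths[["vitreous"]])
  expect_length(profs, 3)
  leak <- read_leakage_observations(paths[["leakage"]])
  expect_equal(nrow(leak), 168)
})
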