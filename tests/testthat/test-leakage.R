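obs_df <- function(scores, agent = "aflibercept", day = 26) {
  data.frame(animal_id = paste0("a", seq_along(scores)), agent = agent,
             challenge_day = day, score = scores,
             stringsAsFactors = FALSE)
}

test_that("scores dichotomize at the moderate-to-severe cut", {
  d <- dichotomize(obs_df(c(0, 1, 2, 3, 4)))
  expect_equal(d$binary, c(0L, 0L, 1L, 1L, 1L))
  empty <- data.frame(animal_id = character(0), agent = character(0),
                      challenge_day = numeric(0), score = integer(0))
  expect_equal(nrow(dichotomize(empty)), 0)
  expect_equal(dichotomize(obs_df(c(0, 1)), threshold = 0)$binary,
               c(1L, 1L))
  expect_error(dichotomize(obs_df(c(-1, 2))), "nonnegative")
  expect_error(dichotomize(obs_df(c(0.5, 2))), "integers")
})

test_that("the vehicle week-10 exclusion fires and is logged", {
  d <- rbind(obs_df(c(3, 2), agent = "vehicle", day = 68),
             obs_df(c(3, 2), agent = "vehicle", day = 54),
             obs_df(c(0, 1), agent = "aflibercept", day = 68))
  res <- apply_exclusions(d)
  expect_equal(nrow(res$excluded), 2)
  expect_true(all(res$excluded$agent == "vehicle" &
                    res$excluded$challenge_day == 68))
  expect_equal(unique(res$excluded$rule), "vehicle_week10")
  expect_equal(nrow(res$observations), 4)
  # no matching records or no rules: identity
  clean <- obs_df(c(1, 2))
  expect_equal(apply_exclusions(clean)$observations, clean)
  expect_equal(apply_exclusions(d, rules = list())$observations, d)
})

test_that("two-point construction solves the logistic exactly", {
  m <- leakage_logistic_from_points(46, 0.2, 94, 0.8)
  expect_equal(m$x50, 70, tolerance = 1e-12)
  expect_equal(m$slope, 24 / log(4), tolerance = 1e-12)
  expect_equal(backcalc_free_vegf(m, 0.5), 70, tolerance = 1e-12)
  # the three exposure estimates are equally spaced by logit symmetry
  x <- backcalc_free_vegf(m, c(0.2, 0.5, 0.8))
  expect_equal(diff(x), c(24, 24), tolerance = 1e-10)
  # constraining through (46, 0.2) and (70, 0.5) returns 94 at p = 0.8
  m2 <- leakage_logistic_from_points(46, 0.2, 70, 0.5)
  expect_equal(backcalc_free_vegf(m2, 0.8), 94, tolerance = 1e-12)
})

test_that("back-calculation is the exact inverse of the forward model", {
  m <- leakage_logistic(70, 17.312)
  p <- c(1e-6, 0.01, 0.2, 0.5, 0.8, 0.99, 1 - 1e-6)
  expect_equal(predict(m, backcalc_free_vegf(m, p)), p, tolerance = 1e-12)
  expect_error(backcalc_free_vegf(m, 0), "strictly between")
  expect_error(backcalc_free_vegf(m, 1), "strictly between")
})

test_that("maximum-likelihood fit recovers symmetric and simulated truths", {
  # perfectly balanced outcomes symmetric around x = 50
  x <- rep(c(30, 40, 60, 70), each = 10)
  y <- c(rep(0:1, c(8, 2)), rep(0:1, c(6, 4)), rep(0:1, c(4, 6)),
         rep(0:1, c(2, 8)))
  fit <- fit_leakage_logistic(data.frame(percent_free = x, binary = y))
  expect_equal(fit$x50, 50, tolerance = 1e-6)

  # seeded Bernoulli draws at the study scale (n = 294) recover the truth
  set.seed(294)
  truth <- leakage_logistic(70, 24 / log(4))
  xs <- runif(294, 0, 100)
  ys <- rbinom(294, 1, predict(truth, xs))
  fit2 <- fit_leakage_logistic(data.frame(percent_free = xs, binary = ys))
  expect_lt(abs(fit2$x50 - 70), 5)
  expect_gt(fit2$slope, 0)

  one_class <- data.frame(percent_free = xs[1:10], binary = rep(1L, 10))
  expect_error(fit_leakage_logistic(one_class), "both outcome classes")
})

test_that("cluster-robust errors widen under within-animal correlation", {
  set.seed(77)
  truth <- leakage_logistic(70, 24 / log(4))
  n_animal <- 40
  xs <- rep(runif(n_animal, 20, 100), each = 2)
  id <- rep(paste0("r", seq_len(n_animal)), each = 2)
  # perfectly correlated duplicate outcomes per animal
  y1 <- rbinom(n_animal, 1, predict(truth, xs[seq(1, 80, by = 2)]))
  d <- data.frame(animal_id = id, percent_free = xs, binary = rep(y1, each = 2))
  f_iid <- fit_leakage_logistic(d)
  f_cl <- fit_leakage_logistic(d, cluster_robust = TRUE)
  expect_equal(f_cl$x50, f_iid$x50)          # point estimate unchanged
  expect_gt(f_cl$se_x50, f_iid$se_x50)       # duplicated info inflates naive SE
  # elbow readout is just the low-probability back-calculation
  expect_equal(leakage_elbow(f_iid, 0.1),
               backcalc_free_vegf(f_iid, 0.1))
  expect_lt(leakage_elbow(f_iid), f_iid$x50)
})

test_that("complete separation is flagged, not silently reported", {
  d <- data.frame(percent_free = c(1:10, 90:99),
                  binary = rep(c(0L, 1L), each = 10))
  expect_warning(fit <- fit_leakage_logistic(d), "separation")
  expect_true(fit$separation)
  expect_equal(fit$accuracy, 1)
})

test_that("accuracy behaves as a proper complement and ignores labels", {
  d <- data.frame(percent_free = c(10, 20, 80, 90),
                  binary = c(0L, 0L, 1L, 1L),
                  animal_id = c("a", "b", "c", "d"))
  m <- leakage_logistic(50, 10)
  expect_equal(classification_accuracy(m, d), 1)
  # anti-model: flip outcomes, accuracy complements
  d_flip <- d
  d_flip$binary <- 1L - d$binary
  expect_equal(classification_accuracy(m, d_flip),
               1 - classification_accuracy(m, d))
  # relabeling animals changes nothing
  d_relab <- d
  d_relab$animal_id <- sample(letters[5:8])
  expect_equal(classification_accuracy(m, d_relab),
               classification_accuracy(m, d))
})
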