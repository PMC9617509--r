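#' Dichotomize ordinal leakage scores
#'
#' Fluorescein-angiography leakage scores are split into no-to-mild
#' (score < 2, binary 0) and moderate-to-severe (score >= 2, binary 1).
#'
#' @param observations data.frame with a nonnegative integer `score` column.
#' @param threshold score at and above which leakage is moderate-to-severe.
#' @return The data.frame with a `binary` column set (0/1).
#' @export
dichotomize <- function(observations, threshold = 2) {
  stopifnot(is.data.frame(observations))
  if (nrow(observations) == 0L) {
    observations$binary <- integer(0)
    return(observations)
  }
  s <- observations$score
  if (any(s < 0) || any(s != round(s))) {
    stop("'score' must contain nonnegative integers", call. = FALSE)
  }
  observations$binary <- as.integer(s >= threshold)
  observations
}

#' Default exclusion rules for leakage observations
#'
#' The single default rule drops vehicle observations at study week 10
#' (challenge day 68), where unusually low control leakage makes the vehicle
#' anchor unreliable. Study week is `(challenge_day + 2) / 7`.
#'
#' @return Named list of predicate functions taking the observation
#'   data.frame and returning a logical drop mask.
#' @export
default_exclusion_rules <- function() {
  list(vehicle_week10 = function(df) {
    df$agent == "vehicle" & (df$challenge_day + 2) / 7 >= 10
  })
}

#' Apply exclusion rules to leakage observations
#'
#' @param observations leakage observation data.frame (columns `agent`,
#'   `challenge_day`, ...).
#' @param rules named list of predicate functions; default
#'   [default_exclusion_rules()]. An empty list is the identity.
#' @return List with `observations` (kept rows) and `excluded` (dropped rows
#'   with a `rule` column naming the rule that fired).
#' @export
apply_exclusions <- function(observations, rules = default_exclusion_rules()) {
  stopifnot(is.data.frame(observations))
  drop <- rep(FALSE, nrow(observations))
  fired <- rep(NA_character_, nrow(observations))
  for (nm in names(rules)) {
    hit <- rules[[nm]](observations)
    if (!is.logical(hit) || length(hit) != nrow(observations)) {
      stop(sprintf("rule '%s' did not return a logical mask", nm),
           call. = FALSE)
    }
    fired[hit & !drop] <- nm
    drop <- drop | hit
  }
  excluded <- observations[drop, , drop = FALSE]
  if (nrow(excluded) > 0L) excluded$rule <- fired[drop]
  list(observations = observations[!drop, , drop = FALSE],
       excluded = excluded)
}

#' Two-parameter leakage logistic model
#'
#' `p(x) = 1 / (1 + exp(-(x - x50) / slope))` linking the percent free VEGF
#' `x` in the observation window to the probability of moderate-to-severe
#' leakage. `x50` is the free-VEGF percentage at probability one half and
#' `slope` the width of the transition in percentage points per logit; this
#' parameterization makes back-calculated exposure tables directly
#' interpretable. The conventional intercept/coefficient form is
#' `intercept = -x50/slope`, `coefficient = 1/slope` (see
#' [logistic_coefficients()]).
#'
#' @param x50 percent free VEGF at p = 0.5.
#' @param slope transition width, percent per logit (> 0).
#' @param fit_method label recording how the model was obtained.
#' @param n_obs number of observations behind a fitted model.
#' @param accuracy in-sample classification accuracy, if computed.
#' @param separation logical; TRUE when the fit hit complete separation.
#' @return An object of class `leakage_logistic`.
#' @export
leakage_logistic <- function(x50, slope, fit_method = "specified",
                             n_obs = NA_integer_, accuracy = NA_real_,
                             separation = FALSE) {
  check_positive(slope = slope)
  stopifnot(is.finite(x50))
  structure(list(x50 = x50, slope = slope, fit_method = fit_method,
                 n_obs = n_obs, accuracy = accuracy,
                 separation = separation),
            class = "leakage_logistic")
}

#' @export
print.leakage_logistic <- function(x, ...) {
  cat(sprintf("<leakage_logistic> x50 = %.4g%% free VEGF, slope = %.4g (%s)\n",
              x$x50, x$slope, x$fit_method))
  if (!is.na(x$accuracy)) {
    cat(sprintf("  in-sample accuracy %.3f on %d observations\n",
                x$accuracy, x$n_obs))
  }
  invisible(x)
}

#' Predicted leakage probability
#'
#' @param object a [leakage_logistic()] model.
#' @param percent_free percent free VEGF value(s).
#' @param ... unused.
#' @return Probability of moderate-to-severe leakage.
#' @export
predict.leakage_logistic <- function(object, percent_free, ...) {
  stats::plogis((percent_free - object$x50) / object$slope)
}

#' Construct the logistic exactly through two exposure-probability points
#'
#' Solves the two-parameter model exactly for two constraints
#' `(x1, p1)` and `(x2, p2)`: `slope = (x2 - x1) / (logit(p2) - logit(p1))`
#' and `x50 = x1 - slope * logit(p1)`.
#'
#' @param x1,p1,x2,p2 the two constraints; probabilities strictly in (0, 1).
#' @return A [leakage_logistic()] model.
#' @examples
#' m <- leakage_logistic_from_points(46, 0.2, 94, 0.8)
#' backcalc_free_vegf(m, 0.5) # 70
#' @export
leakage_logistic_from_points <- function(x1, p1, x2, p2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p1 != p2, x1 != x2)
  slope <- (x2 - x1) / (stats::qlogis(p2) - stats::qlogis(p1))
  if (slope <= 0) {
    stop("constraints imply a non-increasing logistic (slope <= 0)",
         call. = FALSE)
  }
  leakage_logistic(x50 = x1 - slope * stats::qlogis(p1), slope = slope,
                   fit_method = "two-point")
}

#' Fit the leakage logistic by Bernoulli maximum likelihood
#'
#' Fits `p(x) = 1/(1 + exp(-(x - x50)/slope))` to dichotomized leakage
#' observations with model-assigned `percent_free` values, via binomial GLM
#' maximum likelihood. Repeated observations of one animal are treated as
#' independent Bernoulli trials. Complete separation is detected and
#' flagged; the returned boundary parameters are then not meaningful beyond
#' the separating threshold.
#'
#' @param observations data.frame with numeric `percent_free` and 0/1
#'   `binary` columns (see [dichotomize()]).
#' @param cluster_robust logical; when `TRUE`, standard errors of `x50` and
#'   `slope` are computed with a cluster-robust (animal-level) sandwich
#'   covariance using the `animal_id` column, acknowledging that repeated
#'   observations of one animal are correlated. Off by default to match the
#'   independent-trials analysis the model reconstructs.
#' @return A fitted [leakage_logistic()] with in-sample accuracy at the 0.5
#'   cutoff and, if estimable, delta-method `se_x50` and `se_slope` fields.
#' @export
fit_leakage_logistic <- function(observations, cluster_robust = FALSE) {
  stopifnot(is.data.frame(observations),
            all(c("percent_free", "binary") %in% names(observations)))
  y <- observations$binary
  x <- observations$percent_free
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present to fit the logistic",
         call. = FALSE)
  }
  # geometric separation check: in one dimension the classes are completely
  # separated iff their supports do not overlap
  sep <- max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (!is.finite(cf[[2L]]) || cf[[2L]] <= 0) {
    stop("fitted slope is not positive; leakage does not increase with ",
         "free VEGF in these data", call. = FALSE)
  }
  slope <- 1 / cf[[2L]]
  x50 <- -cf[[1L]] / cf[[2L]]
  model <- leakage_logistic(x50 = x50, slope = slope, fit_method = "ml",
                            n_obs = length(y), separation = sep)
  V <- if (cluster_robust) {
    if (!"animal_id" %in% names(observations)) {
      stop("cluster-robust errors need an 'animal_id' column", call. = FALSE)
    }
    sandwich::vcovCL(fit, cluster = observations$animal_id)
  } else stats::vcov(fit)
  if (all(is.finite(V))) {
    # delta method on (x50, slope) = (-a/b, 1/b)
    a <- cf[[1L]]; b <- cf[[2L]]
    g_x50 <- c(-1 / b, a / b^2)
    g_slope <- c(0, -1 / b^2)
    model$se_x50 <- sqrt(drop(t(g_x50) %*% V %*% g_x50))
    model$se_slope <- sqrt(drop(t(g_slope) %*% V %*% g_slope))
  }
  if (sep) {
    warning("complete or quasi-complete separation: logistic parameters ",
            "are at the boundary", call. = FALSE)
  }
  model$accuracy <- classification_accuracy(model, observations)
  model
}

#' Back-calculate the free-VEGF percentage at a given probability
#'
#' Exact inverse of the fitted logistic:
#' `x = x50 + slope * log(p / (1 - p))`.
#'
#' @param model a [leakage_logistic()].
#' @param p probability (strictly between 0 and 1); vectorized.
#' @return Percent free VEGF.
#' @export
backcalc_free_vegf <- function(model, p) {
  stopifnot(inherits(model, "leakage_logistic"))
  if (any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly between 0 and 1", call. = FALSE)
  }
  model$x50 + model$slope * stats::qlogis(p)
}

#' Free-VEGF level at which leakage risk starts to rise
#'
#' An interpretive summary: the exposure at a low-probability elbow of the
#' logistic (default p = 0.1), i.e. the percent free VEGF above which the
#' probability of moderate-to-severe leakage begins to increase steeply.
#'
#' @param model a [leakage_logistic()].
#' @param p elbow probability.
#' @return Percent free VEGF.
#' @export
leakage_elbow <- function(model, p = 0.1) backcalc_free_vegf(model, p)

#' Classification accuracy of a leakage model
#'
#' Fraction of observations whose dichotomized outcome matches the model
#' prediction thresholded at probability 0.5.
#'
#' @param model a [leakage_logistic()].
#' @param observations data.frame with `percent_free` and `binary`.
#' @return Accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(model, observations) {
  stopifnot(inherits(model, "leakage_logistic"),
            all(c("percent_free", "binary") %in% names(observations)))
  pred <- as.integer(predict(model, observations$percent_free) >= 0.5)
  mean(pred == observations$binary)
}

#' Read leakage observations from delimited text
#'
#' Expects columns `animal_id`, `agent`, `challenge_day`, `score` and
#' optionally `percent_free`.
#'
#' @param path CSV file path.
#' @return Observation data.frame (not yet dichotomized).
#' @export
read_leakage_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "agent", "challenge_day", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("missing column '%s' in '%s'", miss[[1L]], path),
         call. = FALSE)
  }
  df
}
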