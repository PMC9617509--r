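#' Free fraction of inhibitor at solution equilibrium
#'
#' Solves the 1:1 site-level mass balance of a homogeneous one-site binding
#' equilibrium for the fraction of inhibitor binding sites left unbound. This
#' is the quantity a kinetic exclusion assay probes: a brief bead-capture
#' step samples the free inhibitor without perturbing the equilibrium.
#'
#' With inhibitor sites `I`, ligand sites `L` and dissociation constant `K`,
#' the free fraction is the positive root of the mass-balance quadratic:
#' `f = ((I - L - K) + sqrt((I - L - K)^2 + 4 K I)) / (2 I)`.
#'
#' @param inhibitor_total total inhibitor binding-site concentration (molar).
#' @param ligand_total total ligand (titrant) site concentration (molar); may
#'   be a vector.
#' @param kd equilibrium dissociation constant (molar).
#' @return Free fraction(s) in `[0, 1]`.
#' @examples
#' equilibrium_free_fraction(100e-12, 50e-12, 1.3e-12)
#' @export
equilibrium_free_fraction <- function(inhibitor_total, ligand_total, kd) {
  check_positive(inhibitor_total = inhibitor_total, kd = kd)
  check_nonnegative(ligand_total = ligand_total)
  b <- inhibitor_total - ligand_total - kd
  s <- sqrt(b * b + 4 * kd * inhibitor_total)
  # the textbook root (b + s) cancels catastrophically when b << 0; the
  # algebraically identical form 2K/(s - b) is stable there
  f <- ifelse(b >= 0,
              (b + s) / (2 * inhibitor_total),
              2 * kd / (s - b) / 1)
  pmin(pmax(f, 0), 1)
}

#' One equilibrium titration curve
#'
#' Container for a single KinExA-style titration: the ligand (VEGF-A165) is
#' titrated against a constant inhibitor concentration and the free-inhibitor
#' signal recorded.
#'
#' @param constant_conc fixed inhibitor site concentration (molar).
#' @param titrant_concs strictly positive, sorted titrant site
#'   concentrations (molar).
#' @param signals measured signals, same length as `titrant_concs`.
#' @param replicate_id curve label.
#' @return An object of class `binding_curve`.
#' @export
binding_curve <- function(constant_conc, titrant_concs, signals,
                          replicate_id = "curve1") {
  check_positive(constant_conc = constant_conc,
                 titrant_concs = titrant_concs)
  if (is.unsorted(titrant_concs)) {
    stop("'titrant_concs' must be sorted increasing", call. = FALSE)
  }
  if (length(signals) != length(titrant_concs)) {
    stop("'signals' and 'titrant_concs' must have equal length",
         call. = FALSE)
  }
  structure(list(constant_conc = constant_conc,
                 titrant_concs = titrant_concs,
                 signals = as.numeric(signals),
                 replicate_id = as.character(replicate_id)),
            class = "binding_curve")
}

#' Predicted KinExA signal for one curve
#'
#' Signal model: `background + amplitude * free_fraction`, optionally scaled
#' by a per-curve linear drift across injection order,
#' `1 + drift * u` with `u` centered on `[-1/2, 1/2]`. Drift is a declared
#' instrument-trend correction; its functional form is a package choice.
#'
#' @param curve a [binding_curve()] (signals ignored).
#' @param kd dissociation constant (molar).
#' @param amplitude signal span.
#' @param background signal at full saturation.
#' @param drift relative linear drift over the injection series (0 = none).
#' @return Numeric vector of predicted signals.
#' @export
kinexa_signal <- function(curve, kd, amplitude = 1, background = 0,
                          drift = 0) {
  stopifnot(inherits(curve, "binding_curve"))
  f <- equilibrium_free_fraction(curve$constant_conc, curve$titrant_concs, kd)
  n <- length(f)
  u <- if (n > 1L) (seq_len(n) - 1) / (n - 1) - 0.5 else 0
  (background + amplitude * f) * (1 + drift * u)
}

# sum of squares for a fixed kd: per curve the model is linear in
# (background, amplitude) so nuisance parameters are profiled in closed form;
# with drift enabled a 1-D inner optimisation over the drift slope is added
.ncurve_profile <- function(kd, curves, use_drift = FALSE) {
  total <- 0
  pars <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    f <- equilibrium_free_fraction(cv$constant_conc, cv$titrant_concs, kd)
    y <- cv$signals
    n <- length(y)
    u <- if (n > 1L) (seq_len(n) - 1) / (n - 1) - 0.5 else 0
    solve_lin <- function(d) {
      scale <- 1 + d * u
      X <- cbind(scale, scale * f)
      fit <- stats::lm.fit(X, y)
      list(ss = sum(fit$residuals^2),
           background = fit$coefficients[[1L]],
           amplitude = fit$coefficients[[2L]])
    }
    if (use_drift) {
      op <- stats::optimize(function(d) solve_lin(d)$ss,
                            interval = c(-0.8, 0.8))
      sol <- solve_lin(op$minimum)
      sol$drift <- op$minimum
    } else {
      sol <- solve_lin(0)
      sol$drift <- 0
    }
    pars[[i]] <- sol
    total <- total + sol$ss
  }
  list(ss = total, pars = pars)
}

#' Global N-curve fit of a shared K_D
#'
#' Fits the one-site homogeneous binding model globally across several
#' titration curves run at different constant inhibitor concentrations: one
#' shared dissociation constant, with amplitude and background (and
#' optionally a linear drift) free per curve. Running curves at two or more
#' constant concentrations constrains K_D far better than any single curve.
#'
#' The objective is least squares. For a trial K_D the per-curve nuisance
#' parameters are linear and profiled out exactly, leaving a 1-D problem in
#' `log10(K_D)` solved by a fixed multi-start grid plus local refinement;
#' ties go to the smaller K_D, making the fit deterministic.
#'
#' @param curves list of [binding_curve()] objects (at least one; at least
#'   5 points each).
#' @param use_drift logical; enable the per-curve drift term.
#' @param conf_level confidence level for the profile-likelihood interval,
#'   or `NA` to skip it.
#' @param kd_grid multi-start grid for K_D (molar); default 15 log-spaced
#'   starts over `1e-16`-`1e-9` M.
#' @return An object of class `affinity_fit` with elements `kd`,
#'   `kd_ci_low`, `kd_ci_high`, `per_curve_amplitude`,
#'   `per_curve_background`, `per_curve_drift`, `residual_sum`, `n_obs`,
#'   `n_par`, `ci_open`.
#' @export
fit_ncurve <- function(curves, use_drift = FALSE, conf_level = 0.95,
                       kd_grid = 10^seq(-16, -9, length.out = 15)) {
  if (inherits(curves, "binding_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "binding_curve")))
  npts <- vapply(curves, function(cv) length(cv$signals), integer(1))
  if (any(npts < 5L)) stop("each curve needs at least 5 points", call. = FALSE)
  spans <- vapply(curves, function(cv) diff(range(cv$signals)), numeric(1))
  scale <- max(abs(unlist(lapply(curves, `[[`, "signals"))), 1e-300)
  if (all(spans <= 1e-9 * scale)) {
    stop("fit error: no signal variation across titration (flat curves); ",
         "amplitude is not identifiable", call. = FALSE)
  }

  obj <- function(log10_kd) .ncurve_profile(10^log10_kd, curves, use_drift)$ss
  lg <- log10(kd_grid)
  vals <- vapply(lg, obj, numeric(1))
  best <- which.min(vals)
  lo <- if (best > 1L) lg[best - 1L] else lg[best] - 1
  hi <- if (best < length(lg)) lg[best + 1L] else lg[best] + 1
  op <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-10)
  # deterministic winner: smaller kd on (near-)ties
  cand <- rbind(c(op$minimum, op$objective), c(lg[best], vals[best]))
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  log10_kd <- cand[1, 1]
  kd <- 10^log10_kd

  prof <- .ncurve_profile(kd, curves, use_drift)
  amps <- vapply(prof$pars, `[[`, numeric(1), "amplitude")
  if (max(abs(amps)) <= 1e-6 * scale) {
    stop("fit error: fitted amplitude is zero; binding signal absent",
         call. = FALSE)
  }
  fit <- structure(list(
    kd = kd,
    kd_ci_low = NA_real_,
    kd_ci_high = NA_real_,
    per_curve_amplitude = amps,
    per_curve_background = vapply(prof$pars, `[[`, numeric(1), "background"),
    per_curve_drift = vapply(prof$pars, `[[`, numeric(1), "drift"),
    residual_sum = prof$ss,
    n_obs = sum(npts),
    n_par = 1L + (2L + as.integer(use_drift)) * length(curves),
    use_drift = use_drift,
    ci_open = FALSE,
    conf_level = conf_level
  ), class = "affinity_fit")
  if (!is.na(conf_level)) {
    ci <- kd_confidence_interval(fit, curves, level = conf_level)
    fit$kd_ci_low <- ci[["low"]]
    fit$kd_ci_high <- ci[["high"]]
    fit$ci_open <- isTRUE(attr(ci, "open"))
  }
  fit
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat(sprintf("<affinity_fit> K_D = %.4g M (%.0f%% CI %.4g-%.4g), SSR %.4g, n = %d\n",
              x$kd, 100 * (x$conf_level %||% 0.95), x$kd_ci_low,
              x$kd_ci_high, x$residual_sum, x$n_obs))
  invisible(x)
}

#' Profile-likelihood confidence interval for a fitted K_D
#'
#' Scans K_D over a log grid around the estimate, re-optimizing the per-curve
#' nuisance parameters at every point, and bounds the interval where the
#' residual sum of squares crosses the F-statistic threshold
#' `SSR_min * (1 + qf(level, 1, df) / df)`. Crossings are located by linear
#' interpolation in log10(K_D). If the profile never crosses the threshold on
#' one side, that bound is left open (attribute `open = TRUE`) rather than
#' fabricated.
#'
#' @param fit an [fit_ncurve()] result.
#' @param curves the curves the fit was computed from.
#' @param level confidence level (default 0.95).
#' @param span decades scanned either side of the estimate.
#' @param n_grid number of scan points.
#' @return Named numeric vector `c(low, high)` (molar) with attribute `open`.
#' @export
kd_confidence_interval <- function(fit, curves, level = 0.95, span = 3,
                                   n_grid = 121) {
  stopifnot(inherits(fit, "affinity_fit"), level > 0, level < 1)
  if (inherits(curves, "binding_curve")) curves <- list(curves)
  df <- fit$n_obs - fit$n_par
  if (df < 1L) stop("no residual degrees of freedom for an interval",
                    call. = FALSE)
  thresh <- fit$residual_sum * (1 + stats::qf(level, 1, df) / df)
  lg0 <- log10(fit$kd)
  lg <- seq(lg0 - span, lg0 + span, length.out = n_grid)
  ss <- vapply(lg, function(l) .ncurve_profile(10^l, curves,
                                               fit$use_drift)$ss, numeric(1))
  inside <- ss <= thresh
  # noiseless data: SSR_min ~ 0 and the profile is razor thin; fall back to
  # the grid cell containing the estimate
  if (!any(inside)) inside[which.min(abs(lg - lg0))] <- TRUE
  idx <- range(which(inside))
  open_low <- idx[1L] == 1L
  open_high <- idx[2L] == n_grid
  interp <- function(i_in, i_out) {
    # linear interpolation of the crossing between grid neighbours
    l1 <- lg[i_out]; l2 <- lg[i_in]; s1 <- ss[i_out]; s2 <- ss[i_in]
    if (!is.finite(s1) || s1 == s2) return(l2)
    l1 + (thresh - s1) / (s2 - s1) * (l2 - l1)
  }
  low <- if (open_low) 10^lg[1L] else 10^interp(idx[1L], idx[1L] - 1L)
  high <- if (open_high) 10^lg[n_grid] else 10^interp(idx[2L], idx[2L] + 1L)
  out <- c(low = min(low, fit$kd), high = max(high, fit$kd))
  attr(out, "open") <- open_low || open_high
  out
}

#' Read titration curves from delimited text
#'
#' Expects columns `curve_id`, `constant_conc_molar`, `titrant_conc_molar`,
#' `signal`.
#'
#' @param path CSV file path.
#' @return List of [binding_curve()] objects, one per `curve_id`.
#' @export
read_binding_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "constant_conc_molar", "titrant_conc_molar", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("missing column '%s' in '%s'", miss[[1L]], path),
         call. = FALSE)
  }
  lapply(split(df, df$curve_id), function(d) {
    d <- d[order(d$titrant_conc_molar), ]
    binding_curve(d$constant_conc_molar[[1L]], d$titrant_conc_molar,
                  d$signal, replicate_id = d$curve_id[[1L]])
  })
}

#' Write titration curves to delimited text
#'
#' @param curves list of [binding_curve()] objects.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_binding_curves <- function(curves, path) {
  if (inherits(curves, "binding_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(curve_id = cv$replicate_id,
               constant_conc_molar = cv$constant_conc,
               titrant_conc_molar = cv$titrant_concs,
               signal = cv$signals)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
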