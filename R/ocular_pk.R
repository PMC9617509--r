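#' Hydrodynamic radius from molecular weight
#'
#' Power-law size scaling `r_h = prefactor * MW^exponent`. The default
#' exponent 1/3 is compact-globule scaling; the prefactor only sets the
#' absolute scale and cancels out of calibrated half-life ratios.
#'
#' @param molecular_weight molecular weight in kDa.
#' @param prefactor scale factor (nm per kDa^exponent).
#' @param exponent scaling exponent.
#' @return Hydrodynamic radius in nm.
#' @export
hydrodynamic_radius <- function(molecular_weight, prefactor = 1,
                                exponent = 1 / 3) {
  check_positive(molecular_weight = molecular_weight, prefactor = prefactor)
  prefactor * molecular_weight^exponent
}

#' Parameters of the anterior-elimination ocular PK model
#'
#' The minimal physiology-based model assumes biologics leave the vitreous
#' predominantly by the anterior route: diffusion through the vitreous into
#' the anterior chamber, then washout with aqueous humor turnover. The
#' vitreous-to-aqueous transfer rate of a molecule scales inversely with its
#' hydrodynamic radius (diffusion limited); `geometry_factor` is the single
#' calibration constant that absorbs eye geometry.
#'
#' @param hydrodynamic_radius molecule radius, nm.
#' @param transfer_rate_vit_to_aq vitreous-to-aqueous first-order rate, 1/day.
#' @param aqueous_elimination_rate anterior-chamber washout rate, 1/day.
#' @param geometry_factor calibration constant (nm/day), so that
#'   `transfer_rate = geometry_factor / r_h`.
#' @return An object of class `pk_model_params`.
#' @export
pk_model_params <- function(hydrodynamic_radius, transfer_rate_vit_to_aq,
                            aqueous_elimination_rate, geometry_factor) {
  check_positive(hydrodynamic_radius = hydrodynamic_radius,
                 transfer_rate_vit_to_aq = transfer_rate_vit_to_aq,
                 aqueous_elimination_rate = aqueous_elimination_rate,
                 geometry_factor = geometry_factor)
  structure(list(hydrodynamic_radius = hydrodynamic_radius,
                 transfer_rate_vit_to_aq = transfer_rate_vit_to_aq,
                 aqueous_elimination_rate = aqueous_elimination_rate,
                 geometry_factor = geometry_factor),
            class = "pk_model_params")
}

.aqueous_rate <- function(geometry) {
  # outflow uL/min over anterior-chamber volume -> first-order washout, 1/day
  ul_min_to_ml_day(geometry$aqueous_outflow) / geometry$aqueous_volume
}

#' Calibrate the anterior-elimination model against one reference agent
#'
#' Fixes the geometry factor so that the model reproduces a reference
#' vitreal half-life for a molecule of known size; every other molecule's
#' half-life then follows from its hydrodynamic radius alone.
#'
#' @param geometry an [eye_geometry()].
#' @param anchor_mw reference molecular weight, kDa.
#' @param anchor_half_life reference vitreal half-life, days.
#' @param prefactor,exponent size-scaling parameters, see
#'   [hydrodynamic_radius()].
#' @return A calibration object of class `anterior_pk_model`.
#' @export
calibrate_anterior_model <- function(geometry, anchor_mw, anchor_half_life,
                                     prefactor = 1, exponent = 1 / 3) {
  stopifnot(inherits(geometry, "eye_geometry"))
  check_positive(anchor_mw = anchor_mw, anchor_half_life = anchor_half_life)
  k_aq <- .aqueous_rate(geometry)
  k_vt <- log(2) / anchor_half_life
  if (k_vt >= k_aq) {
    stop("reference half-life is faster than aqueous turnover; the ",
         "anterior-dominated calibration is invalid for this geometry",
         call. = FALSE)
  }
  r_anchor <- hydrodynamic_radius(anchor_mw, prefactor, exponent)
  structure(list(geometry = geometry,
                 prefactor = prefactor,
                 exponent = exponent,
                 geometry_factor = k_vt * r_anchor,
                 aqueous_elimination_rate = k_aq,
                 anchor_mw = anchor_mw,
                 anchor_half_life = anchor_half_life),
            class = "anterior_pk_model")
}

#' Predict vitreal half-life from molecular size
#'
#' Solves the two-compartment linear system (vitreous -> anterior chamber ->
#' outflow) for a molecule of the given size and returns `ln 2` over the
#' slowest eigenvalue. In the anterior-dominated limit (aqueous turnover much
#' faster than vitreous transfer) the half-life is proportional to the
#' hydrodynamic radius.
#'
#' @param molecular_weight molecular weight in kDa (or an [agent_spec()]).
#' @param model an [calibrate_anterior_model()] calibration, or a
#'   [pk_model_params()] with absolute rates (then `molecular_weight` is
#'   ignored for the transfer rate).
#' @return Predicted vitreal half-life in days.
#' @examples
#' m <- calibrate_anterior_model(eye_geometry(), anchor_mw = 48,
#'                               anchor_half_life = 3.8)
#' predict_vitreal_half_life(26, m) # ~3.1 days
#' @export
predict_vitreal_half_life <- function(molecular_weight, model) {
  if (inherits(molecular_weight, "agent_spec")) {
    molecular_weight <- molecular_weight$molecular_weight
  }
  if (inherits(model, "anterior_pk_model")) {
    r_h <- hydrodynamic_radius(molecular_weight, model$prefactor,
                               model$exponent)
    k_vt <- model$geometry_factor / r_h
    k_aq <- model$aqueous_elimination_rate
  } else if (inherits(model, "pk_model_params")) {
    k_vt <- model$transfer_rate_vit_to_aq
    k_aq <- model$aqueous_elimination_rate
  } else {
    stop("supply either a calibrated 'anterior_pk_model' or absolute ",
         "'pk_model_params'", call. = FALSE)
  }
  A <- matrix(c(-k_vt, 0,
                k_vt, -k_aq), nrow = 2, byrow = TRUE)
  ev <- eigen(A, only.values = TRUE)$values
  slow <- min(abs(Re(ev)))
  log(2) / slow
}

#' Vitreous concentration-time profile
#'
#' @param times sampling days (non-negative, sorted by construction).
#' @param concentrations concentrations, ug/mL.
#' @param lloq assay lower limit of quantification, ug/mL.
#' @param agent agent label.
#' @param source `"observed"` or `"simulated"`.
#' @param animal_id optional per-row animal labels (destructive sampling).
#' @return An object of class `concentration_profile` (a data.frame with
#'   columns `animal_id`, `day`, `conc`, `below_lloq` and attributes `lloq`,
#'   `agent`, `source`).
#' @export
concentration_profile <- function(times, concentrations, lloq,
                                  agent = "agent",
                                  source = c("simulated", "observed"),
                                  animal_id = NULL) {
  source <- match.arg(source)
  check_nonnegative(times = times, concentrations = concentrations)
  check_positive(lloq = lloq)
  if (length(times) != length(concentrations)) {
    stop("'times' and 'concentrations' must have equal length", call. = FALSE)
  }
  if (is.null(animal_id)) animal_id <- rep("pooled", length(times))
  ord <- order(times)
  df <- data.frame(animal_id = as.character(animal_id)[ord],
                   day = times[ord],
                   conc = concentrations[ord],
                   below_lloq = concentrations[ord] < lloq,
                   stringsAsFactors = FALSE)
  structure(df, lloq = lloq, agent = agent, source = source,
            class = c("concentration_profile", "data.frame"))
}

#' Simulate a destructive-sampling vitreous PK study
#'
#' Monoexponential decay from `C0 = dose / vitreous volume` with lognormal
#' inter-animal variability; each sampled eye contributes a single terminal
#' time point, as in a destructive-sampling rabbit study. Concentrations
#' below the assay LLOQ are flagged, not altered.
#'
#' @param agent an [agent_spec()].
#' @param geometry an [eye_geometry()].
#' @param t_half vitreal half-life, days.
#' @param schedule sampling days.
#' @param n_per_day animals sampled per day.
#' @param noise_cv lognormal coefficient of variation (0 = deterministic).
#' @param lloq assay LLOQ, ug/mL.
#' @param seed optional RNG seed for reproducibility.
#' @return A [concentration_profile()].
#' @export
simulate_profile <- function(agent, geometry, t_half,
                             schedule = c(5, 26, 33, 40, 54, 56),
                             n_per_day = 7, noise_cv = 0.15,
                             lloq = 0.00625, seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"), inherits(geometry, "eye_geometry"))
  check_positive(t_half = t_half, n_per_day = n_per_day)
  check_nonnegative(noise_cv = noise_cv, schedule = schedule)
  if (!is.null(seed)) set.seed(seed)
  c0 <- agent$dose_mass / geometry$vitreous_volume
  days <- rep(schedule, each = n_per_day)
  mu <- c0 * 2^(-days / t_half)
  conc <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else mu
  ids <- sprintf("%s_d%02d_a%d", agent$name, rep(seq_along(schedule),
                                                 each = n_per_day),
                 rep(seq_len(n_per_day), times = length(schedule)))
  concentration_profile(days, conc, lloq = lloq, agent = agent$name,
                        source = "simulated", animal_id = ids)
}

#' Read a vitreous concentration table
#'
#' Expects columns `animal_id`, `agent`, `day`, `conc_ug_per_ml` and
#' optionally `flag` (ignored on read; LLOQ flags are recomputed from
#' `lloq`).
#'
#' @param path CSV file path.
#' @param lloq assay LLOQ, ug/mL.
#' @return Named list of [concentration_profile()] objects, one per agent.
#' @export
read_concentration_profiles <- function(path, lloq = 0.00625) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "agent", "day", "conc_ug_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("missing column '%s' in '%s'", miss[[1L]], path),
         call. = FALSE)
  }
  lloq_tab <- if ("lloq" %in% names(df)) {
    tapply(df$lloq, df$agent, `[[`, 1L)
  } else NULL
  lapply(split(df, df$agent), function(d) {
    lq <- if (!is.null(lloq_tab)) lloq_tab[[d$agent[[1L]]]] else lloq
    concentration_profile(d$day, d$conc_ug_per_ml, lloq = lq,
                          agent = d$agent[[1L]], source = "observed",
                          animal_id = d$animal_id)
  })
}

#' Write vitreous concentration profiles
#'
#' @param profiles a [concentration_profile()] or list of them.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_concentration_profiles <- function(profiles, path) {
  if (inherits(profiles, "concentration_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(animal_id = p$animal_id, agent = attr(p, "agent"),
               day = p$day, conc_ug_per_ml = p$conc,
               flag = as.integer(p$below_lloq), lloq = attr(p, "lloq"))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
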