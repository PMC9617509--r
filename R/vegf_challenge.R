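#' Binding and elimination rate constants for the challenge simulation
#'
#' Rate constants, all in canonical nM/day units, governing the intravitreal
#' drug + VEGF + complex system after a VEGF challenge: reversible binding
#' (`k_on`, `k_off = k_on * K_D`) and first-order ocular elimination of each
#' species by the anterior route.
#'
#' @param k_on association rate, 1/(nM day).
#' @param kd dissociation constant at body temperature, nM.
#' @param k_el_drug,k_el_vegf,k_el_complex elimination rates, 1/day.
#' @return An object of class `binding_kinetics_params`.
#' @export
binding_kinetics_params <- function(k_on, kd, k_el_drug, k_el_vegf,
                                    k_el_complex) {
  check_positive(k_on = k_on, kd = kd, k_el_drug = k_el_drug,
                 k_el_vegf = k_el_vegf, k_el_complex = k_el_complex)
  structure(list(k_on = k_on, k_off = k_on * kd, kd = kd,
                 k_el_drug = k_el_drug, k_el_vegf = k_el_vegf,
                 k_el_complex = k_el_complex),
            class = "binding_kinetics_params")
}

#' Default challenge kinetics for an agent
#'
#' Builds [binding_kinetics_params()] for one agent from its affinity and
#' the size-scaling PK model: the drug eliminates with its own vitreal
#' half-life (observed if available, else size-predicted), while the VEGF
#' dimer and the drug-VEGF complex eliminate with half-lives predicted from
#' their molecular weights through the same anterior-route model. The
#' association rate defaults to the diffusion-limited class value
#' 1e6 / (M s).
#'
#' @param agent an [agent_spec()].
#' @param pk_model a calibration from [calibrate_anterior_model()].
#' @param design a [challenge_design()] (for the VEGF molecular weight).
#' @param k_on_per_M_s association rate in 1/(M s).
#' @param drug_half_life override for the drug's vitreal half-life, days.
#' @return A [binding_kinetics_params()].
#' @export
default_binding_params <- function(agent, pk_model, design = challenge_design(),
                                   k_on_per_M_s = 1e6,
                                   drug_half_life = NULL) {
  stopifnot(inherits(agent, "agent_spec"),
            inherits(pk_model, "anterior_pk_model"))
  t_drug <- drug_half_life %||%
    (if (!is.na(agent$vitreal_half_life)) agent$vitreal_half_life
     else predict_vitreal_half_life(agent$molecular_weight, pk_model))
  t_vegf <- predict_vitreal_half_life(design$vegf_molecular_weight, pk_model)
  # complex composition: one VEGF dimer plus as many drug molecules as it
  # has drug-binding sites
  mw_complex <- design$vegf_molecular_weight +
    agent$sites_per_vegf * agent$molecular_weight
  t_complex <- predict_vitreal_half_life(mw_complex, pk_model)
  kd_body_nM <- agent$kd_assay * agent$kd_temp_factor * 1e9
  k_on <- k_on_per_M_s * 86400 / 1e9  # 1/(M s) -> 1/(nM day)
  binding_kinetics_params(k_on = k_on, kd = kd_body_nM,
                          k_el_drug = log(2) / t_drug,
                          k_el_vegf = log(2) / t_vegf,
                          k_el_complex = log(2) / t_complex)
}

# quadratic equilibrium partition of site totals into complex
.equilibrium_complex <- function(d_tot, v_tot, kd) {
  b <- d_tot + v_tot + kd
  disc <- b * b - 4 * d_tot * v_tot
  disc[disc < 0] <- 0
  # stable smaller root: 2DV / (b + sqrt(disc))
  ifelse(d_tot + v_tot <= 0, 0, 2 * d_tot * v_tot / (b + sqrt(disc)))
}

#' Simulate drug-VEGF binding kinetics in the vitreous
#'
#' Integrates the three-species mass-action system (free drug sites `D`,
#' free VEGF sites `V`, complex `C`):
#' `dD/dt = -k_el_drug D - k_on D V + k_off C`,
#' `dV/dt = -k_el_vegf V - k_on D V + k_off C`,
#' `dC/dt = -k_el_complex C + k_on D V - k_off C`.
#'
#' Two modes are provided. `"equilibrium"` (the default, and much faster)
#' assumes binding is fast relative to elimination: it integrates only the
#' species totals with species-specific elimination and partitions them
#' algebraically at each step through the mass-balance quadratic.
#' `"kinetic"` integrates the full stiff ODE (deSolve `lsoda`, relative
#' tolerance 1e-8) and serves as the verification oracle for the
#' quasi-equilibrium approximation.
#'
#' @param drug0 initial free drug site concentration, nM.
#' @param vegf0 initial free VEGF site concentration, nM.
#' @param params a [binding_kinetics_params()].
#' @param duration simulated time, days.
#' @param mode `"equilibrium"` or `"kinetic"`.
#' @param n_steps output grid resolution.
#' @return A data.frame with columns `time`, `drug_free`, `vegf_free`,
#'   `complex`.
#' @export
simulate_binding_kinetics <- function(drug0, vegf0, params, duration,
                                      mode = c("equilibrium", "kinetic"),
                                      n_steps = 201) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "binding_kinetics_params"))
  check_nonnegative(drug0 = drug0, vegf0 = vegf0)
  check_positive(duration = duration)
  # quadratically stretched grid: dense near t = 0 so the fast binding
  # transient after the VEGF bolus is resolved by the trapezoid quadrature
  times <- duration * seq(0, 1, length.out = n_steps)^2
  if (mode == "kinetic") {
    rhs <- function(t, y, p) {
      D <- y[1L]; V <- y[2L]; C <- y[3L]
      bind <- p$k_on * D * V - p$k_off * C
      list(c(-p$k_el_drug * D - bind,
             -p$k_el_vegf * V - bind,
             -p$k_el_complex * C + bind))
    }
    atol <- 1e-12 * max(drug0, vegf0, 1)
    sol <- deSolve::lsoda(c(D = drug0, V = vegf0, C = 0), times, rhs,
                          parms = params, rtol = 1e-8, atol = atol)
    if (attr(sol, "istate")[[1L]] < 0) {
      stop(sprintf("integration failure at t=%.3g (last state D=%.3g V=%.3g C=%.3g)",
                   sol[nrow(sol), 1L], sol[nrow(sol), 2L],
                   sol[nrow(sol), 3L], sol[nrow(sol), 4L]), call. = FALSE)
    }
    out <- data.frame(time = sol[, "time"],
                      drug_free = pmax(sol[, "D"], 0),
                      vegf_free = pmax(sol[, "V"], 0),
                      complex = pmax(sol[, "C"], 0))
  } else {
    rhs <- function(t, y, p) {
      dt <- max(y[1L], 0); vt <- max(y[2L], 0)
      C <- .equilibrium_complex(dt, vt, p$kd)
      list(c(-p$k_el_drug * (dt - C) - p$k_el_complex * C,
             -p$k_el_vegf * (vt - C) - p$k_el_complex * C))
    }
    sol <- deSolve::lsoda(c(Dt = drug0, Vt = vegf0), times, rhs,
                          parms = params, rtol = 1e-8,
                          atol = 1e-12 * max(drug0, vegf0, 1))
    if (attr(sol, "istate")[[1L]] < 0) {
      stop("integration failure in equilibrium mode", call. = FALSE)
    }
    d_tot <- pmax(sol[, "Dt"], 0)
    v_tot <- pmax(sol[, "Vt"], 0)
    C <- .equilibrium_complex(d_tot, v_tot, params$kd)
    out <- data.frame(time = sol[, "time"],
                      drug_free = pmax(d_tot - C, 0),
                      vegf_free = pmax(v_tot - C, 0),
                      complex = C)
  }
  out
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Free-VEGF exposure in the observation window, relative to vehicle
#'
#' Runs the challenge simulation from VEGF injection to the leakage
#' observation (default lag 47 h) and integrates the free-VEGF concentration
#' by the trapezoid rule on the solver grid. The same simulation with
#' `drug0 = 0` defines the vehicle exposure (100% free VEGF); the result is
#' the percentage ratio.
#'
#' @param agent an [agent_spec()].
#' @param geometry an [eye_geometry()] (sets the VEGF challenge
#'   concentration).
#' @param design a [challenge_design()].
#' @param params a [binding_kinetics_params()].
#' @param drug_conc_nM free drug site concentration at the time of the
#'   challenge, nM.
#' @param mode integration mode, see [simulate_binding_kinetics()].
#' @return An object of class `free_vegf_result`: `auc_free`,
#'   `auc_free_vehicle` (day nM), `percent_free`, `window_start`,
#'   `window_end` (days since challenge).
#' @export
percent_free_vegf <- function(agent, geometry, design, params, drug_conc_nM,
                              mode = c("equilibrium", "kinetic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "challenge_design"))
  check_nonnegative(drug_conc_nM = drug_conc_nM)
  vegf0 <- mass_to_nM(design$vegf_dose_mass / 1000,
                      design$vegf_molecular_weight,
                      geometry$vitreous_volume) * agent$sites_per_vegf
  window <- hours_to_days(design$observation_lag)
  run_auc <- function(d0) {
    tr <- simulate_binding_kinetics(d0, vegf0, params, duration = window,
                                    mode = mode)
    .trapz(tr$time, tr$vegf_free)
  }
  auc_free <- run_auc(drug_conc_nM)
  auc_vehicle <- run_auc(0)
  structure(list(auc_free = auc_free,
                 auc_free_vehicle = auc_vehicle,
                 percent_free = 100 * auc_free / auc_vehicle,
                 window_start = 0,
                 window_end = window),
            class = "free_vegf_result")
}

#' Predicted protection over the challenge schedule
#'
#' For each challenge day, decays the drug from its day-0 vitreous
#' concentration with its vitreal half-life, computes the free-VEGF exposure
#' of that challenge and maps it through the leakage logistic model to a
#' probability of moderate-to-severe leakage.
#'
#' @param agent an [agent_spec()].
#' @param geometry an [eye_geometry()].
#' @param design a [challenge_design()]; `challenge_days` may be overridden
#'   with `days`.
#' @param leakage_model a [leakage_logistic()] model.
#' @param pk_model a [calibrate_anterior_model()] calibration (used for the
#'   VEGF/complex elimination rates and, absent an observed value, the drug
#'   half-life).
#' @param days optional challenge-day grid replacing the design schedule.
#' @param t_half optional override of the drug's vitreal half-life, days.
#' @param mode integration mode.
#' @return A data.frame: `agent`, `challenge_day`, `drug_conc_nM`,
#'   `percent_free`, `probability`.
#' @export
protection_timecourse <- function(agent, geometry, design, leakage_model,
                                  pk_model, days = NULL, t_half = NULL,
                                  mode = "equilibrium") {
  days <- days %||% design$challenge_days
  t_half <- t_half %||%
    (if (!is.na(agent$vitreal_half_life)) agent$vitreal_half_life
     else predict_vitreal_half_life(agent$molecular_weight, pk_model))
  params <- default_binding_params(agent, pk_model, design,
                                   drug_half_life = t_half)
  c0_sites <- mass_to_nM(agent$dose_mass, agent$molecular_weight,
                         geometry$vitreous_volume) *
    agent$binding_sites_per_drug
  res <- lapply(days, function(d) {
    d0 <- c0_sites * 2^(-d / t_half)
    pf <- percent_free_vegf(agent, geometry, design, params, d0, mode = mode)
    data.frame(agent = agent$name, challenge_day = d, drug_conc_nM = d0,
               percent_free = pf$percent_free,
               probability = predict(leakage_model, pf$percent_free))
  })
  do.call(rbind, res)
}

#' Search for the discriminating challenge window
#'
#' Scans a day grid for the contiguous range in which the agents'
#' predicted leakage probabilities are mutually separated (minimum pairwise
#' gap above `margin`) and which contains every agent's 0.5-probability
#' crossing; such a range is where a challenge discriminates the agents.
#' `margin = 0` gives the widest window; increasing it shrinks the window
#' monotonically. If no qualifying range exists an empty window is returned.
#'
#' @param agents list of [agent_spec()] objects (at least two).
#' @param geometry an [eye_geometry()].
#' @param design a [challenge_design()].
#' @param leakage_model a [leakage_logistic()] model.
#' @param pk_model a [calibrate_anterior_model()] calibration.
#' @param day_grid candidate challenge days.
#' @param margin minimum pairwise probability separation.
#' @param mode integration mode.
#' @return List with `start_day`, `end_day` (NA when empty), `empty` flag and
#'   `crossings` (named vector of interpolated 0.5-crossing days).
#' @export
find_design_window <- function(agents, geometry, design, leakage_model,
                               pk_model, day_grid = seq(1, 70, by = 1),
                               margin = 0, mode = "equilibrium") {
  stopifnot(length(agents) >= 2L)
  check_nonnegative(margin = margin)
  probs <- sapply(agents, function(ag) {
    protection_timecourse(ag, geometry, design, leakage_model, pk_model,
                          days = day_grid, mode = mode)$probability
  })
  crossings <- apply(probs, 2, function(p) {
    i <- which(p >= 0.5)[1L]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(day_grid[1L])
    # linear interpolation of the 0.5 crossing
    day_grid[i - 1L] + (0.5 - p[i - 1L]) / (p[i] - p[i - 1L]) *
      (day_grid[i] - day_grid[i - 1L])
  })
  names(crossings) <- vapply(agents, `[[`, character(1), "name")
  empty <- list(start_day = NA_real_, end_day = NA_real_, empty = TRUE,
                crossings = crossings)
  if (any(is.na(crossings))) return(empty)
  gaps <- apply(probs, 1, function(p) min(dist(p)))
  ok <- gaps > margin
  if (!any(ok)) return(empty)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values)) {
    lo <- day_grid[starts[j]]; hi <- day_grid[ends[j]]
    if (all(crossings >= lo & crossings <= hi)) {
      return(list(start_day = lo, end_day = hi, empty = FALSE,
                  crossings = crossings))
    }
  }
  empty
}
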