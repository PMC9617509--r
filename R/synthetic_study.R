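#' Synthetic study specification
#'
#' Gathers everything the synthetic-data generators need to emulate the
#' head-to-head rabbit study: the agents, the eye geometry, the challenge
#' schedule, the assay noise levels and the generating truth of the leakage
#' logistic. A fixed seed makes every generator byte-reproducible.
#'
#' @param seed integer RNG seed.
#' @param agents list of [agent_spec()] objects.
#' @param geometry an [eye_geometry()].
#' @param design a [challenge_design()].
#' @param noise_cv_pk lognormal inter-animal CV of vitreous concentrations.
#' @param noise_cv_binding multiplicative CV of KinExA signals.
#' @param leakage_truth numeric `c(x50, slope)` generating the binary
#'   leakage outcomes.
#' @param animals_per_group animals per agent per time point.
#' @param observation_jitter half-width (hours) of the uniform jitter on the
#'   47-h observation lag, emulating the protocol's 47 +/- 3 h.
#' @param pk_sampling_days destructive PK sampling days (cohort
#'   terminations).
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(seed = 1,
                                 agents = default_agents(),
                                 geometry = eye_geometry(),
                                 design = challenge_design(),
                                 noise_cv_pk = 0.15,
                                 noise_cv_binding = 0.02,
                                 leakage_truth = c(x50 = 70, slope = 24 / log(4)),
                                 animals_per_group = 7,
                                 observation_jitter = 3,
                                 pk_sampling_days = c(5, 26, 33, 40, 54, 56)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  check_positive(animals_per_group = animals_per_group)
  check_nonnegative(noise_cv_pk = noise_cv_pk,
                    noise_cv_binding = noise_cv_binding,
                    observation_jitter = observation_jitter)
  structure(list(seed = as.integer(seed), agents = agents,
                 geometry = geometry, design = design,
                 noise_cv_pk = noise_cv_pk,
                 noise_cv_binding = noise_cv_binding,
                 leakage_truth = leakage_truth,
                 animals_per_group = animals_per_group,
                 observation_jitter = observation_jitter,
                 pk_sampling_days = pk_sampling_days),
            class = "synthetic_study_spec")
}

# stage- and agent-specific but reproducible sub-seed below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h) %% 2147483647L)
}

# KinExA concentration designs: constant-partner levels (molar), top titrant
# concentration and the 3-fold dilution count spanning the assay's range
.kinexa_designs <- list(
  aflibercept = list(constants = c(2.5e-12, 5e-12, 50e-12),
                     top = 1e-9, n_levels = 10L),
  brolucizumab = list(constants = c(25e-12, 50e-12, 400e-12),
                      top = 4e-9, n_levels = 10L),
  ranibizumab = list(constants = c(50e-12, 400e-12),
                     top = 10e-9, n_levels = 9L)
)

#' KinExA concentration design for an agent
#'
#' Returns the constant-partner concentrations and 3-fold titrant series
#' used to generate synthetic KinExA curves. The three study agents use
#' their assay designs; any other agent gets a generic K_D-controlled design
#' (constants at 10x and 100x K_D, titration from 1e4 x K_D downward).
#'
#' @param agent an [agent_spec()].
#' @return List with `constants` (molar) and `titrants` (molar, increasing).
#' @export
kinexa_design <- function(agent) {
  d <- .kinexa_designs[[agent$name]]
  if (is.null(d)) {
    d <- list(constants = agent$kd_assay * c(10, 100),
              top = agent$kd_assay * 1e4, n_levels = 10L)
  }
  titrants <- sort(d$top / 3^(seq_len(d$n_levels) - 1L))
  list(constants = d$constants, titrants = titrants)
}

#' Generate synthetic KinExA titration curves for one agent
#'
#' Duplicate equilibrium titration curves at the agent's constant-partner
#' concentrations, on the 3-fold titrant series, with the agent's assay K_D
#' as generating truth and multiplicative Gaussian signal noise
#' (`spec$noise_cv_binding`, default 2%). Signals use unit amplitude and
#' zero background.
#'
#' @param spec a [synthetic_study_spec()].
#' @param agent an [agent_spec()] (one of `spec$agents`).
#' @param n_replicates curves per constant concentration.
#' @return List of [binding_curve()] objects.
#' @export
generate_kinexa_dataset <- function(spec, agent, n_replicates = 2) {
  stopifnot(inherits(spec, "synthetic_study_spec"),
            inherits(agent, "agent_spec"))
  set.seed(derive_seed(spec$seed, paste0("kinexa_", agent$name)))
  des <- kinexa_design(agent)
  kd <- agent$kd_assay
  curves <- list()
  for (i in seq_along(des$constants)) {
    for (r in seq_len(n_replicates)) {
      cv <- binding_curve(des$constants[[i]], des$titrants,
                          signals = rep(0, length(des$titrants)),
                          replicate_id = sprintf("%s_c%d_r%d", agent$name,
                                                 i, r))
      mu <- kinexa_signal(cv, kd, amplitude = 1, background = 0)
      noise <- if (spec$noise_cv_binding > 0) {
        stats::rnorm(length(mu), 1, spec$noise_cv_binding)
      } else 1
      cv$signals <- mu * noise
      curves[[length(curves) + 1L]] <- cv
    }
  }
  curves
}

.default_lloq <- c(aflibercept = 6.25e-3, brolucizumab = 20e-3,
                   ranibizumab = 3e-3)  # ug/mL

#' Assay LLOQ for an agent
#'
#' Lower limit of quantification of the agent's vitreous bioanalytical
#' assay, in ug/mL (aflibercept 6.25, brolucizumab 20, ranibizumab 3 ng/mL;
#' 6.25 ng/mL for unknown agents).
#'
#' @param agent an [agent_spec()] or agent name.
#' @return LLOQ in ug/mL.
#' @export
assay_lloq <- function(agent) {
  nm <- if (inherits(agent, "agent_spec")) agent$name else agent
  unname(.default_lloq[nm] %|na|% 6.25e-3)
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Generate synthetic destructive-sampling vitreous PK profiles
#'
#' One profile per agent: monoexponential decay from `dose / vitreous
#' volume` at the agent's reference vitreal half-life, sampled destructively
#' at the cohort termination days with `spec$animals_per_group` animals per
#' day, lognormal inter-animal variability and censoring flags at each
#' agent's assay LLOQ.
#'
#' @param spec a [synthetic_study_spec()].
#' @return Named list of [concentration_profile()] objects.
#' @export
generate_vitreous_pk_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  out <- lapply(spec$agents, function(ag) {
    if (is.na(ag$vitreal_half_life)) {
      stop(sprintf("agent '%s' has no reference vitreal half-life", ag$name),
           call. = FALSE)
    }
    simulate_profile(ag, spec$geometry, t_half = ag$vitreal_half_life,
                     schedule = spec$pk_sampling_days,
                     n_per_day = spec$animals_per_group,
                     noise_cv = spec$noise_cv_pk,
                     lloq = assay_lloq(ag),
                     seed = derive_seed(spec$seed, paste0("pk_", ag$name)))
  })
  names(out) <- vapply(spec$agents, `[[`, character(1), "name")
  out
}

#' Generate synthetic leakage observations
#'
#' For every agent x challenge day x animal, computes the model-assigned
#' percent free VEGF (drug decayed to the challenge day, challenge
#' simulated over the observation window) and draws the binary
#' moderate-to-severe outcome from the generating logistic truth. A vehicle
#' arm at 100% free VEGF is included. Animals are assigned (first, final)
#' challenge-day pairs so no animal is challenged more than twice, matching
#' the cohort structure of the in vivo design. Ordinal scores are
#' synthesized as 3 for positive outcomes and 0 or 1 (equally likely) for
#' negative ones; only the score >= 2 cut carries information.
#'
#' Each animal's leakage readout happens at `observation_lag` plus a uniform
#' jitter of up to `spec$observation_jitter` hours (the protocol's 47 +/- 3
#' h); the model-assigned `percent_free` uses that animal's actual window.
#'
#' @param spec a [synthetic_study_spec()].
#' @param pk_model optional [calibrate_anterior_model()] calibration; by
#'   default anchored on the first agent with a reference half-life.
#' @param mode integration mode for the challenge simulation.
#' @return A leakage observation data.frame: `animal_id`, `agent`,
#'   `challenge_day`, `observation_hours`, `score`, `percent_free`.
#' @export
generate_leakage_dataset <- function(spec, pk_model = NULL,
                                     mode = "equilibrium") {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  truth <- leakage_logistic(spec$leakage_truth[[1L]], spec$leakage_truth[[2L]],
                            fit_method = "truth")
  pk_model <- pk_model %||% default_pk_calibration(spec$agents, spec$geometry)
  design <- spec$design
  days <- design$challenge_days
  n_days <- length(days)
  n_animals <- spec$animals_per_group
  # (first, final) cohort pairing: day i shares animals with day i + ceil(n/2)
  half <- ceiling(n_days / 2)
  cohort_of <- ((seq_len(n_days) - 1L) %% half) + 1L
  rows <- list()
  arms <- c(spec$agents, list(vehicle = NULL))
  for (arm in names(arms)) {
    ag <- arms[[arm]]
    set.seed(derive_seed(spec$seed, paste0("leakage_", arm)))
    jit <- matrix(stats::runif(n_days * n_animals, -spec$observation_jitter,
                               spec$observation_jitter),
                  nrow = n_days)
    if (!is.null(ag)) {
      t_half <- if (!is.na(ag$vitreal_half_life)) ag$vitreal_half_life else
        predict_vitreal_half_life(ag$molecular_weight, pk_model)
      params <- default_binding_params(ag, pk_model, design,
                                       drug_half_life = t_half)
      c0_sites <- mass_to_nM(ag$dose_mass, ag$molecular_weight,
                             spec$geometry$vitreous_volume) *
        ag$binding_sites_per_drug
    }
    for (i in seq_len(n_days)) {
      lag_h <- design$observation_lag + jit[i, ]
      pf <- if (is.null(ag)) rep(100, n_animals) else {
        d0 <- c0_sites * 2^(-days[[i]] / t_half)
        vapply(lag_h, function(lh) {
          dsn <- design
          dsn$observation_lag <- lh
          percent_free_vegf(ag, spec$geometry, dsn, params, d0,
                            mode = mode)$percent_free
        }, numeric(1))
      }
      p <- predict(truth, pf)
      binary <- stats::rbinom(n_animals, 1, p)
      score <- ifelse(binary == 1, 3L, stats::rbinom(n_animals, 1, 0.5))
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("%s_c%d_a%d", arm, cohort_of[[i]],
                            seq_len(n_animals)),
        agent = arm,
        challenge_day = days[[i]],
        observation_hours = lag_h,
        score = as.integer(score),
        percent_free = pf,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default anterior-model calibration for a set of agents
#'
#' Anchors the size-scaling half-life model on ranibizumab's reference
#' half-life when present, else on the first agent carrying one.
#'
#' @param agents list of [agent_spec()] objects.
#' @param geometry an [eye_geometry()].
#' @return A [calibrate_anterior_model()] calibration.
#' @export
default_pk_calibration <- function(agents, geometry = eye_geometry()) {
  nms <- vapply(agents, `[[`, character(1), "name")
  have <- !vapply(agents, function(a) is.na(a$vitreal_half_life), logical(1))
  if (!any(have)) stop("no agent carries a reference vitreal half-life",
                       call. = FALSE)
  pick <- if ("ranibizumab" %in% nms[have]) {
    which(nms == "ranibizumab")
  } else which(have)[1L]
  anchor <- agents[[pick]]
  calibrate_anterior_model(geometry, anchor$molecular_weight,
                           anchor$vitreal_half_life)
}

#' Write the three synthetic study datasets
#'
#' Generates and writes the KinExA curves, vitreous PK table and leakage
#' observations of a synthetic study as delimited text.
#'
#' @param spec a [synthetic_study_spec()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_synthetic_study <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- unlist(lapply(spec$agents, function(ag)
    generate_kinexa_dataset(spec, ag)), recursive = FALSE)
  paths <- c(
    kinexa = file.path(out_dir, "kinexa_curves.csv"),
    vitreous = file.path(out_dir, "vitreous_pk.csv"),
    leakage = file.path(out_dir, "leakage_scores.csv")
  )
  write_binding_curves(curves, paths[["kinexa"]])
  write_concentration_profiles(generate_vitreous_pk_dataset(spec),
                               paths[["vitreous"]])
  utils::write.csv(generate_leakage_dataset(spec), paths[["leakage"]],
                   row.names = FALSE)
  invisible(paths)
}
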