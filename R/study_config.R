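#' Anti-VEGF agent specification
#'
#' Bundles the molecular and dosing parameters of one intravitreal anti-VEGF
#' agent. Molecular weights and binding stoichiometries are not assay outputs;
#' the shipped defaults (see [default_agents()]) are literature-sourced and
#' overridable through the study configuration file.
#'
#' @param name agent label, e.g. `"aflibercept"`.
#' @param molecular_weight molecular weight in kDa.
#' @param dose_mass intravitreal dose in micrograms.
#' @param injection_volume injection volume in microlitres.
#' @param kd_assay equilibrium dissociation constant (mol/L) at the assay
#'   temperature (23 C).
#' @param kd_temp_factor dimensionless multiplier taking the assay-temperature
#'   K_D to body temperature. Default 1 (no correction); the hook exists
#'   because solution affinities are temperature dependent.
#' @param binding_sites_per_drug VEGF-binding sites per drug molecule (1 or 2).
#' @param sites_per_vegf drug-binding sites per VEGF-A165 dimer (1 or 2). A
#'   trap that sequesters a whole dimer has 1; a Fab/scFv binding each
#'   protomer has 2.
#' @param ic50_nM optional cell-potency IC50 (nM) used as simulation truth by
#'   the pipeline; `NA` to omit.
#' @param vitreal_half_life optional observed vitreal half-life in days used
#'   as a PK reference; `NA` to omit.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(name, molecular_weight, dose_mass,
                       injection_volume = 25, kd_assay,
                       kd_temp_factor = 1,
                       binding_sites_per_drug = 1, sites_per_vegf = 2,
                       ic50_nM = NA_real_, vitreal_half_life = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_positive(molecular_weight = molecular_weight, dose_mass = dose_mass,
                 injection_volume = injection_volume, kd_assay = kd_assay,
                 kd_temp_factor = kd_temp_factor)
  if (!binding_sites_per_drug %in% c(1, 2)) {
    stop("'binding_sites_per_drug' must be 1 or 2", call. = FALSE)
  }
  if (!sites_per_vegf %in% c(1, 2)) {
    stop("'sites_per_vegf' must be 1 or 2", call. = FALSE)
  }
  if (!is.na(ic50_nM)) check_positive(ic50_nM = ic50_nM)
  if (!is.na(vitreal_half_life)) {
    check_positive(vitreal_half_life = vitreal_half_life)
  }
  structure(list(
    name = name,
    molecular_weight = molecular_weight,
    dose_mass = dose_mass,
    injection_volume = injection_volume,
    kd_assay = kd_assay,
    kd_temp_factor = kd_temp_factor,
    binding_sites_per_drug = binding_sites_per_drug,
    sites_per_vegf = sites_per_vegf,
    ic50_nM = ic50_nM,
    vitreal_half_life = vitreal_half_life
  ), class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("<agent_spec> %s: %g kDa, dose %g ug, K_D(assay) %.3g M\n",
              x$name, x$molecular_weight, x$dose_mass, x$kd_assay))
  invisible(x)
}

#' Rabbit eye geometry
#'
#' Geometric and physiological constants of the rabbit eye used by the
#' anterior-elimination pharmacokinetic model. Defaults are
#' implementer-chosen values within the physiological ranges reported for
#' the rabbit (vitreous volume 1.15-1.7 mL).
#'
#' @param vitreous_volume vitreous humor volume, mL.
#' @param aqueous_volume anterior-chamber aqueous volume, mL.
#' @param aqueous_outflow aqueous humor turnover, uL/min.
#' @param diffusion_path_length characteristic vitreous diffusion length, cm.
#' @param temperature body temperature, K.
#' @param vitreous_viscosity vitreous viscosity, Pa s.
#' @return An object of class `eye_geometry`.
#' @export
eye_geometry <- function(vitreous_volume = 1.5, aqueous_volume = 0.3,
                         aqueous_outflow = 3, diffusion_path_length = 0.9,
                         temperature = 310.15, vitreous_viscosity = 7e-4) {
  check_positive(vitreous_volume = vitreous_volume,
                 aqueous_volume = aqueous_volume,
                 aqueous_outflow = aqueous_outflow,
                 diffusion_path_length = diffusion_path_length,
                 temperature = temperature,
                 vitreous_viscosity = vitreous_viscosity)
  if (vitreous_volume < 0.5 || vitreous_volume > 3) {
    stop("'vitreous_volume' outside plausible rabbit range (mL)",
         call. = FALSE)
  }
  structure(list(
    vitreous_volume = vitreous_volume,
    aqueous_volume = aqueous_volume,
    aqueous_outflow = aqueous_outflow,
    diffusion_path_length = diffusion_path_length,
    temperature = temperature,
    vitreous_viscosity = vitreous_viscosity
  ), class = "eye_geometry")
}

#' Intravitreal VEGF challenge design
#'
#' The schedule and size of the VEGF-challenge study: an intravitreal bolus
#' of recombinant human VEGF-A165 on each challenge day with the leakage
#' readout a fixed lag later.
#'
#' @param vegf_dose_mass VEGF challenge dose, ng.
#' @param vegf_injection_volume challenge injection volume, uL.
#' @param vegf_molecular_weight VEGF-A165 dimer molecular weight, kDa.
#' @param challenge_days strictly increasing day numbers of the challenges.
#' @param observation_lag hours from VEGF injection to leakage observation.
#' @param animals_per_group animals per agent per time point.
#' @return An object of class `challenge_design`.
#' @export
challenge_design <- function(vegf_dose_mass = 500,
                             vegf_injection_volume = 50,
                             vegf_molecular_weight = 38.2,
                             challenge_days = c(5, 26, 33, 40, 54, 68),
                             observation_lag = 47,
                             animals_per_group = 7) {
  check_positive(vegf_dose_mass = vegf_dose_mass,
                 vegf_injection_volume = vegf_injection_volume,
                 vegf_molecular_weight = vegf_molecular_weight,
                 observation_lag = observation_lag,
                 animals_per_group = animals_per_group)
  check_nonnegative(challenge_days = challenge_days)
  if (length(challenge_days) < 1L || is.unsorted(challenge_days, strictly = TRUE)) {
    stop("'challenge_days' must be strictly increasing", call. = FALSE)
  }
  structure(list(
    vegf_dose_mass = vegf_dose_mass,
    vegf_injection_volume = vegf_injection_volume,
    vegf_molecular_weight = vegf_molecular_weight,
    challenge_days = challenge_days,
    observation_lag = observation_lag,
    animals_per_group = animals_per_group
  ), class = "challenge_design")
}

#' Default anti-VEGF agents
#'
#' The three agents of the head-to-head rabbit study with their rabbit-scaled
#' doses (about 50% of the clinical dose in 25 uL) and measured solution
#' affinities. Molecular weights and stoichiometries are literature-sourced
#' defaults, not measurements: aflibercept is a receptor-trap fusion (115 kDa,
#' one trap per VEGF dimer), brolucizumab an scFv (26 kDa) and ranibizumab a
#' Fab (48 kDa), both with one site per drug and two drugs per dimer.
#'
#' @return Named list of [agent_spec()] objects.
#' @export
default_agents <- function() {
  list(
    aflibercept = agent_spec(
      name = "aflibercept", molecular_weight = 115, dose_mass = 1000,
      kd_assay = 171.9e-15, binding_sites_per_drug = 1, sites_per_vegf = 1,
      ic50_nM = 2.42, vitreal_half_life = 5.63),
    brolucizumab = agent_spec(
      name = "brolucizumab", molecular_weight = 26, dose_mass = 3000,
      kd_assay = 1.3e-12, binding_sites_per_drug = 1, sites_per_vegf = 2,
      ic50_nM = 5.74, vitreal_half_life = 3.10),
    ranibizumab = agent_spec(
      name = "ranibizumab", molecular_weight = 48, dose_mass = 250,
      kd_assay = 21.8e-12, binding_sites_per_drug = 1, sites_per_vegf = 2,
      ic50_nM = 10.82, vitreal_half_life = 3.15)
  )
}

#' Default study configuration
#'
#' @return List with elements `agents` (list of [agent_spec()]), `geometry`
#'   ([eye_geometry()]) and `design` ([challenge_design()]).
#' @export
default_study_config <- function() {
  list(agents = default_agents(),
       geometry = eye_geometry(),
       design = challenge_design())
}

.agent_fields <- c("name", "molecular_weight", "dose_mass",
                   "injection_volume", "kd_assay", "kd_temp_factor",
                   "binding_sites_per_drug", "sites_per_vegf",
                   "ic50_nM", "vitreal_half_life")
.agent_required <- c("name", "molecular_weight", "dose_mass", "kd_assay")
.geometry_fields <- c("vitreous_volume", "aqueous_volume", "aqueous_outflow",
                      "diffusion_path_length", "temperature",
                      "vitreous_viscosity")
.design_fields <- c("vegf_dose_mass", "vegf_injection_volume",
                    "vegf_molecular_weight", "challenge_days",
                    "observation_lag", "animals_per_group")

.check_known_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra) > 0L) {
    stop(sprintf("unknown key '%s' in %s", extra[[1L]], where), call. = FALSE)
  }
}

#' Read a study configuration file
#'
#' Parses a YAML study configuration with top-level sections `agents`
#' (a list of agent maps), `geometry` and `design`. Every key is validated;
#' unknown keys and missing mandatory agent fields are rejected with an error
#' naming the offending key. Omitted optional fields take the package
#' defaults.
#'
#' @param path path to a YAML file; see the shipped default at
#'   `system.file("extdata", "default_study.yaml", package = "vitreopkpd")`.
#' @return A configuration list as from [default_study_config()].
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  .check_known_keys(raw, c("agents", "geometry", "design"), "config")
  if (is.null(raw$agents) || length(raw$agents) == 0L) {
    stop("config error: section 'agents' is missing or empty", call. = FALSE)
  }
  agents <- lapply(raw$agents, function(a) {
    .check_known_keys(a, .agent_fields, sprintf("agent '%s'",
                                                a$name %||% "<unnamed>"))
    miss <- setdiff(.agent_required, names(a))
    if (length(miss) > 0L) {
      stop(sprintf("config error: agent missing mandatory field '%s'",
                   miss[[1L]]), call. = FALSE)
    }
    do.call(agent_spec, a)
  })
  names(agents) <- vapply(agents, `[[`, character(1), "name")
  geometry <- if (is.null(raw$geometry)) eye_geometry() else {
    .check_known_keys(raw$geometry, .geometry_fields, "geometry")
    do.call(eye_geometry, raw$geometry)
  }
  design <- if (is.null(raw$design)) challenge_design() else {
    .check_known_keys(raw$design, .design_fields, "design")
    do.call(challenge_design, raw$design)
  }
  list(agents = agents, geometry = geometry, design = design)
}

#' Write a study configuration file
#'
#' Serializes a configuration list to YAML such that
#' `load_study_config(write_study_config(cfg, path))` reproduces `cfg`.
#'
#' @param config configuration list (`agents`, `geometry`, `design`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, function(v) length(v) == 1L && is.na(v), logical(1))]
  }
  out <- list(
    agents = lapply(unname(config$agents), strip),
    geometry = strip(config$geometry),
    design = strip(config$design)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
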