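#' Convert a protein mass to a molar concentration
#'
#' Converts a dose mass dissolved in a given volume to molarity. With the
#' package's boundary units (micrograms, kilodaltons, millilitres) the
#' identity is `1 ug / (1 kDa * 1 mL) = 1e-6 mol/L`.
#'
#' @param mass_ug mass in micrograms.
#' @param molecular_weight_kda molecular weight in kilodaltons.
#' @param volume_ml distribution volume in millilitres.
#' @return Concentration in mol/L.
#' @examples
#' mass_to_molar(1000, 115, 1.5) # aflibercept dose in rabbit vitreous, ~5.8e-6 M
#' @seealso [molar_to_mass()]
#' @export
mass_to_molar <- function(mass_ug, molecular_weight_kda, volume_ml) {
  check_positive(mass_ug = mass_ug,
                 molecular_weight_kda = molecular_weight_kda,
                 volume_ml = volume_ml)
  # ug -> g, kDa -> g/mol, mL -> L
  (mass_ug * 1e-6) / (molecular_weight_kda * 1e3 * volume_ml * 1e-3)
}

#' Convert a molar concentration back to mass
#'
#' Exact inverse of [mass_to_molar()].
#'
#' @param conc_molar concentration in mol/L.
#' @param molecular_weight_kda molecular weight in kilodaltons.
#' @param volume_ml distribution volume in millilitres.
#' @return Mass in micrograms.
#' @export
molar_to_mass <- function(conc_molar, molecular_weight_kda, volume_ml) {
  check_positive(conc_molar = conc_molar,
                 molecular_weight_kda = molecular_weight_kda,
                 volume_ml = volume_ml)
  conc_molar * (molecular_weight_kda * 1e3) * (volume_ml * 1e-3) * 1e6
}

#' @rdname mass_to_molar
#' @details `mass_to_nM()` is a convenience wrapper returning nmol/L, the
#'   package's internal canonical concentration unit.
#' @export
mass_to_nM <- function(mass_ug, molecular_weight_kda, volume_ml) {
  mass_to_molar(mass_ug, molecular_weight_kda, volume_ml) * 1e9
}

#' Convert hours to days
#' @param hours duration in hours.
#' @return Duration in days.
#' @export
hours_to_days <- function(hours) hours / 24

#' Convert an aqueous-humor outflow in uL/min to a volume flow in mL/day
#' @param ul_per_min flow in microlitres per minute.
#' @return Flow in millilitres per day.
#' @export
ul_min_to_ml_day <- function(ul_per_min) ul_per_min * 60 * 24 / 1000

# shared argument validation: every named argument must be finite and > 0
check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("'%s' must be a finite positive number", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# like check_positive but allows zero
check_nonnegative <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
      stop(sprintf("'%s' must be a finite non-negative number", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
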