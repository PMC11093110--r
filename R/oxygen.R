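#' Freshwater oxygen solubility (Benson-Krause)
#'
#' Equilibrium dissolved-oxygen concentration of air-saturated freshwater at
#' 1 atm and salinity 0, from the Benson-Krause fit used by the USGS DOTABLES
#' service. This is the unit bridge between percent air saturation (the native
#' unit of optode respirometry systems) and mg O2 per litre.
#'
#' @param temperature_c Water temperature in degrees Celsius. Must lie in
#'   `[0, 40]`, the validity range of the fit.
#' @return Solubility in mg O2 per litre (same length as `temperature_c`).
#' @examples
#' o2_solubility_mg_per_l(15) # ~10.08
#' o2_solubility_mg_per_l(20) # ~9.09
#' @export
o2_solubility_mg_per_l <- function(temperature_c) {
  if (!is.numeric(temperature_c) || any(!is.finite(temperature_c))) {
    abort("`temperature_c` must be finite numeric.")
  }
  if (any(temperature_c < 0 | temperature_c > 40)) {
    abort("`temperature_c` outside the 0-40 degC validity range of the solubility fit.")
  }
  tk <- temperature_c + 273.15
  exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
        1.2438e10 / tk^3 - 8.621949e11 / tk^4)
}

#' Convert percent air saturation to mg O2 per litre
#'
#' @param percent_sat Dissolved oxygen as percent air saturation (>= 0).
#' @param temperature_c Water temperature in degrees Celsius, in `[0, 40]`.
#' @return Concentration in mg O2 per litre.
#' @examples
#' percent_sat_to_mg_per_l(100, 15)
#' @export
percent_sat_to_mg_per_l <- function(percent_sat, temperature_c) {
  if (!is.numeric(percent_sat) || any(!is.finite(percent_sat)) ||
      any(percent_sat < 0)) {
    abort("`percent_sat` must be finite and >= 0.")
  }
  percent_sat / 100 * o2_solubility_mg_per_l(temperature_c)
}

#' Oxygen uptake rate from a depletion slope
#'
#' Standard closed-respirometry arithmetic: a linear oxygen depletion slope
#' (percent air saturation per second) is converted to a whole-animal oxygen
#' uptake rate in mg O2 per hour using the effective water volume of the
#' system. The effective volume is the total system volume minus the fish's
#' volume, taking fish density as 1 g per mL.
#'
#' @param slope_percent_sat_per_s Depletion slope in percent saturation per
#'   second (negative for uptake).
#' @param temperature_c Water temperature in degrees Celsius.
#' @param system_volume_l Total system (chamber + tubing) volume in litres.
#' @param fish_mass_g Fish mass in grams (displaces water at 1 g/mL).
#' @return Oxygen uptake in mg O2 per hour; positive for depletion.
#' @examples
#' compute_mo2(-0.01, 15, system_volume_l = 0.657, fish_mass_g = 2.62)
#' @export
compute_mo2 <- function(slope_percent_sat_per_s, temperature_c,
                        system_volume_l, fish_mass_g = 0) {
  assert_scalar_number(system_volume_l, "system_volume_l", positive = TRUE)
  if (!is.numeric(fish_mass_g) || any(fish_mass_g < 0)) {
    abort("`fish_mass_g` must be >= 0.")
  }
  effective_volume_l <- system_volume_l - fish_mass_g / 1000
  if (any(effective_volume_l <= 0)) {
    abort("Effective volume <= 0: fish volume exceeds system volume.")
  }
  slope_mg_per_l_per_s <-
    slope_percent_sat_per_s / 100 * o2_solubility_mg_per_l(temperature_c)
  -slope_mg_per_l_per_s * effective_volume_l * 3600
}

# inverse bridge used by the synthetic trace generator
mo2_to_slope_percent_sat <- function(mo2_mg_per_h, temperature_c,
                                     system_volume_l, fish_mass_g = 0) {
  effective_volume_l <- system_volume_l - fish_mass_g / 1000
  -(mo2_mg_per_h / 3600) / (effective_volume_l *
    o2_solubility_mg_per_l(temperature_c) / 100)
}
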