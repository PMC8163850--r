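# Raw gas measurements -> the quantities the partitioning stage consumes:
# MIMS ion currents to Ar-normalised ratios, headspace CO2 to dissolved
# concentration, and an uncalibrated m/z 45/44 delta estimate.

mims_channels <- c(i32 = "i32", i40 = "i40", i44 = "i44", i45 = "i45")

#' Argon-normalised gas ratios from MIMS ion currents
#'
#' Membrane-inlet mass-spectrometer ion currents at m/z 32 (O2), 40 (Ar),
#' 44 (12CO2) and 45 (13CO2) are expressed as ratios to argon, an inert
#' tracer unaffected by biology. No calibration is applied: the ratios are
#' relative trend data for daily monitoring, not quantitative concentrations.
#'
#' @param rec A data frame with columns `day`, `treatment_id`, `i32`, `i40`,
#'   `i44`, `i45` (ion currents, arbitrary units, all > 0).
#' @return A tibble with `day`, `treatment_id`, `o2_ar`, `co2_12_ar`,
#'   `co2_13_ar` and `r13_co2` (= i45/i44).
#' @export
ratios_from_currents <- function(rec) {
  need <- c("day", "treatment_id", names(mims_channels))
  missing <- setdiff(need, names(rec))
  if (length(missing)) stop("missing MIMS columns: ", paste(missing, collapse = ", "))
  cur <- rec[names(mims_channels)]
  if (any(!is.finite(as.matrix(cur))) || any(as.matrix(cur) <= 0))
    stop("all ion currents must be finite and > 0")
  tibble::tibble(
    day = rec$day,
    treatment_id = rec$treatment_id,
    o2_ar = rec$i32 / rec$i40,
    co2_12_ar = rec$i44 / rec$i40,
    co2_13_ar = rec$i45 / rec$i40,
    r13_co2 = rec$i45 / rec$i44
  )
}

#' CO2 solubility K0(T) (Weiss-type fit)
#'
#' Solubility of CO2 in water in mol l-1 atm-1 as a function of temperature
#' and salinity, using the Weiss (1974) fit. Valid for roughly -1 to 40 degC.
#'
#' @param temperature_c Water temperature in degrees Celsius.
#' @param salinity Practical salinity (default 0, fresh water).
#' @return Solubility in mol l-1 atm-1.
#' @export
weiss_k0 <- function(temperature_c, salinity = 0) {
  if (any(temperature_c < -1 | temperature_c > 40))
    stop("temperature outside the solubility fit's validity range (-1 to 40 degC)")
  tk <- temperature_c + 273.15
  lnk0 <- -58.0931 + 90.5069 * (100 / tk) + 22.294 * log(tk / 100) +
    salinity * (0.027766 - 0.025888 * (tk / 100) + 0.0050578 * (tk / 100)^2)
  exp(lnk0)
}

#' Dissolved CO2 concentration from a headspace equilibration
#'
#' A water sample equilibrated with a CO2-free headspace in a sealed vial
#' partitions its CO2 between gas phase (ideal gas) and water phase (Henry's
#' law with the Weiss-type K0). Given the equilibrium headspace mixing ratio,
#' returns the original dissolved concentration of the sample.
#'
#' @param ppm Equilibrium headspace CO2 mixing ratio (umol CO2 per mol air).
#' @param temperature_c Equilibration temperature, degC.
#' @param pressure_atm Total pressure, atm (default 1).
#' @param headspace_ml,water_ml Headspace and water volumes, ml.
#' @param salinity Practical salinity (default 0).
#' @return Dissolved CO2 of the original sample, umol C l-1. Linear and
#'   strictly increasing in `ppm`; with zero headspace it reduces to the
#'   direct Henry's-law concentration K0 * pCO2.
#' @export
dissolved_co2_from_headspace <- function(ppm, temperature_c, pressure_atm = 1,
                                         headspace_ml, water_ml, salinity = 0) {
  stopifnot(all(ppm >= 0), all(ppm < 1e6), headspace_ml >= 0, water_ml > 0,
            pressure_atm > 0)
  r_gas <- 0.082057338     # l atm mol-1 K-1
  tk <- temperature_c + 273.15
  k0 <- weiss_k0(temperature_c, salinity)
  pco2 <- ppm * 1e-6 * pressure_atm                      # atm
  n_gas <- pco2 * (headspace_ml / 1000) / (r_gas * tk)   # mol in headspace
  n_wat <- k0 * pco2 * (water_ml / 1000)                 # mol remaining dissolved
  (n_gas + n_wat) / (water_ml / 1000) * 1e6              # umol l-1
}

#' Trend-level delta-13C from the MIMS 45/44 channel ratio
#'
#' Treats the m/z 45/44 ion-current ratio as the 13C/12C ratio without a
#' 17O correction. With a ~10 atom% labelled substrate the 17O contribution
#' to m/z 45 is negligible relative to signal; at natural abundance this is
#' only a trend-level approximation (documented caveat).
#'
#' @param r45_44 Ion-current ratio m/z 45 over 44 (> 0).
#' @param standard An [iso_standard()]; default [vpdb()].
#' @return An [iso_value()] in delta notation.
#' @export
delta_from_45_44 <- function(r45_44, standard = vpdb()) {
  stopifnot(all(is.finite(r45_44)), all(r45_44 > 0))
  iso_value(ratio_to_delta(r45_44, standard$r13), "delta_permil", standard)
}
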