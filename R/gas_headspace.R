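# Dissolved greenhouse gases from headspace equilibration.
#
# A water sample of volume V_w is shaken with a headspace of ambient air of
# volume V_h; the measured post-equilibration headspace mixing ratio,
# Henry's-law solubility at the equilibration temperature and the ideal gas
# law for the headspace give the original dissolved concentration by mass
# balance. Saturation is always evaluated at the in-situ temperature, which
# in field practice differs from the (warmer) equilibration temperature.

R_GAS_L_ATM <- 0.082057       # L atm / (mol K)
KPA_PER_ATM <- 101.325

# temperature-fit coefficients, ln K0 = a1 + a2*(100/T) + a3*ln(T/100),
# K0 in mol/(L atm) at S = 0 (CH4 via the Bunsen coefficient / 22.414).
# Sources: CO2 Weiss (1974); CH4 Wiesenburg & Guinasso (1979); N2O Weiss &
# Price (1980); O2 from the Garcia & Gordon (1992) refit of Benson & Krause.
.gas_fit <- list(
  CO2 = c(-58.0931, 90.5069, 22.2940),
  CH4 = c(-67.1962, 99.1624, 27.9015),   # Bunsen coefficient fit
  N2O = c(-62.7062, 97.3066, 24.1406)
)
.o2_gg <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)

#' Gas solubility (Henry coefficient) in fresh water
#'
#' Temperature-dependent solubility K0 in mol L-1 atm-1 for CO2, CH4, N2O
#' and O2 at zero salinity (appropriate for dilute lake water, where the
#' salinity effect on solubility is negligible). CO2 and N2O use the
#' standard oceanographic ln-polynomial fits; CH4 is derived from the
#' Bunsen coefficient fit divided by the ideal molar volume 22.414 L/mol;
#' O2 from the Garcia-Gordon refit of the Benson-Krause freshwater data
#' (equilibrium concentration divided by the O2 partial pressure in
#' 1 atm moist air, x_O2 = 0.20946).
#'
#' @param gas one of `"CO2"`, `"CH4"`, `"N2O"`, `"O2"`.
#' @param temperature degC, within 0-30.
#' @param salinity g/kg; retained in the signature for interface clarity
#'   but must be 0 (the freshwater fits shipped here have no salinity
#'   term).
#' @return K0 in mol L-1 atm-1.
#' @export
#' @examples
#' gas_solubility("CO2", 0)   # ~0.0776 mol/(L atm)
gas_solubility <- function(gas, temperature, salinity = 0) {
  gas <- match.arg(gas, c("CO2", "CH4", "N2O", "O2"))
  stop_if_not(all(temperature >= 0 & temperature <= 30),
              "temperature outside solubility-fit validity (0-30 degC)")
  stop_if_not(all(salinity == 0),
              "only S = 0 supported (freshwater fits)")
  TK <- temperature + 273.15
  if (gas == "O2") {
    Ts <- log((298.15 - temperature) / TK)
    Cstar <- exp(.o2_gg[1] + .o2_gg[2] * Ts + .o2_gg[3] * Ts^2 +
                   .o2_gg[4] * Ts^3 + .o2_gg[5] * Ts^4 + .o2_gg[6] * Ts^5)
    return(Cstar * 1e-6 / 0.20946)     # umol/kg -> mol/L per atm O2
  }
  cf <- .gas_fit[[gas]]
  k0 <- exp(cf[1] + cf[2] * (100 / TK) + cf[3] * log(TK / 100))
  if (gas == "CH4") k0 <- k0 / 22.414  # Bunsen (L/L/atm) -> mol/(L atm)
  k0
}

#' A headspace equilibration record
#'
#' @param gas `"CO2"`, `"CH4"` or `"N2O"`.
#' @param depth sampling depth, m.
#' @param measured_ppm headspace mixing ratio after equilibration, ppm.
#' @param ambient_ppm mixing ratio of the ambient air used as headspace,
#'   ppm.
#' @param equilibration_T temperature during shaking, degC.
#' @param in_situ_T lake temperature at the sampling depth, degC.
#' @param water_volume L (default 2.0).
#' @param headspace_volume mL (default 20).
#' @param pressure_kPa atmospheric pressure (default 101.325).
#' @return one-row data.frame of class `headspace_sample`.
#' @export
headspace_sample <- function(gas, depth, measured_ppm, ambient_ppm,
                             equilibration_T, in_situ_T,
                             water_volume = 2.0, headspace_volume = 20,
                             pressure_kPa = 101.325) {
  stop_if_not(all(gas %in% c("CO2", "CH4", "N2O")),
              "gas must be CO2, CH4 or N2O")
  stop_if_not(water_volume > 0 && headspace_volume > 0,
              "volumes must be > 0")
  stop_if_not(all(measured_ppm >= 0) && all(ambient_ppm >= 0),
              "mixing ratios must be >= 0")
  out <- data.frame(gas = gas, depth = depth,
                    measured_ppm = measured_ppm, ambient_ppm = ambient_ppm,
                    equilibration_T = equilibration_T,
                    in_situ_T = in_situ_T,
                    water_volume = water_volume,
                    headspace_volume = headspace_volume,
                    pressure_kPa = pressure_kPa,
                    stringsAsFactors = FALSE)
  class(out) <- c("headspace_sample", class(out))
  out
}

# moles of gas in the headspace at mixing ratio x (ppm), ideal gas law
.headspace_moles <- function(x_ppm, V_h_mL, T_C, P_kPa) {
  (x_ppm * 1e-6) * (P_kPa / KPA_PER_ATM) * (V_h_mL / 1000) /
    (R_GAS_L_ATM * (T_C + 273.15))
}

#' Forward headspace model: dissolved concentration to measured mixing ratio
#'
#' The exact mass-balance counterpart of [invert_headspace()]: given the
#' original dissolved concentration, returns the headspace mixing ratio
#' after complete equilibration. Shared by the synthetic generator so that
#' forward simulation and inversion use one model.
#'
#' @param concentration original dissolved concentration, umol/L.
#' @param gas,ambient_ppm,equilibration_T,water_volume,headspace_volume,pressure_kPa
#'   as in [headspace_sample()].
#' @return equilibrated headspace mixing ratio, ppm.
#' @export
headspace_forward <- function(concentration, gas, ambient_ppm,
                              equilibration_T, water_volume = 2.0,
                              headspace_volume = 20,
                              pressure_kPa = 101.325) {
  stop_if_not(water_volume > 0 && headspace_volume > 0, "volumes must be > 0")
  K0 <- gas_solubility(gas, equilibration_T)
  P_atm <- pressure_kPa / KPA_PER_ATM
  n_total <- concentration * 1e-6 * water_volume +
    .headspace_moles(ambient_ppm, headspace_volume, equilibration_T,
                     pressure_kPa)
  # n_total = x*1e-6*P_atm*K0*V_w + x*1e-6*P_atm*V_h/(R T)
  denom <- 1e-6 * P_atm *
    (K0 * water_volume +
       (headspace_volume / 1000) / (R_GAS_L_ATM * (equilibration_T + 273.15)))
  n_total / denom
}

#' Invert a headspace equilibration to the dissolved gas concentration
#'
#' Mass balance over the bottle: the original dissolved amount equals the
#' post-equilibration dissolved amount (Henry's law at the equilibration
#' temperature and the measured partial pressure) plus the net amount that
#' moved into the headspace (ideal gas law, measured minus ambient mixing
#' ratio), divided by the water volume.
#'
#' @param sample a [headspace_sample()] (multi-row allowed).
#' @return the sample with columns `concentration` (umol/L) and
#'   `flagged_negative` appended.
#' @export
invert_headspace <- function(sample) {
  stop_if_not(inherits(sample, "headspace_sample"),
              "sample must be a headspace_sample")
  conc <- numeric(nrow(sample))
  for (i in seq_len(nrow(sample))) {
    s <- sample[i, ]
    K0 <- gas_solubility(s$gas, s$equilibration_T)
    P_atm <- s$pressure_kPa / KPA_PER_ATM
    p_meas <- s$measured_ppm * 1e-6 * P_atm          # atm
    n_dissolved <- K0 * p_meas * s$water_volume       # mol
    n_transferred <- .headspace_moles(s$measured_ppm - s$ambient_ppm,
                                      s$headspace_volume,
                                      s$equilibration_T, s$pressure_kPa)
    conc[i] <- (n_dissolved + n_transferred) / s$water_volume * 1e6
  }
  sample$concentration <- conc
  sample$flagged_negative <- conc < 0
  if (any(sample$flagged_negative))
    warning("non-physical negative concentrations flagged")
  sample
}

#' Percent saturation relative to air equilibrium
#'
#' 100 * C / C_eq with C_eq = K0(in-situ T) * x_ambient * P, the dissolved
#' concentration in equilibrium with the atmosphere at the in-situ
#' temperature.
#'
#' @param concentration dissolved concentration, umol/L.
#' @param gas gas id (see [gas_solubility()]).
#' @param in_situ_T lake temperature at depth, degC.
#' @param ambient_ppm atmospheric mixing ratio, ppm.
#' @param pressure_kPa atmospheric pressure.
#' @return saturation in percent (100 = air equilibrium).
#' @export
gas_saturation <- function(concentration, gas, in_situ_T, ambient_ppm,
                           pressure_kPa = 101.325) {
  K0 <- gas_solubility(gas, in_situ_T)
  C_eq <- K0 * (ambient_ppm * 1e-6) * (pressure_kPa / KPA_PER_ATM) * 1e6
  stop_if_not(all(C_eq > 0), "equilibrium concentration must be > 0")
  100 * concentration / C_eq
}

#' Areal gas storage in a depth stratum
#'
#' Trapezoidal integration of a concentration profile between two depths,
#' per unit lake area. Where the profile does not reach a bound, the
#' nearest sample is extended as a constant (noted in the attribute
#' `extended`). Units: umol/L integrated over metres gives mmol m-2.
#'
#' @param depth m, strictly increasing.
#' @param concentration umol/L at each depth.
#' @param z_top,z_bottom integration bounds, m.
#' @return storage in mmol m-2 (attribute `extended` TRUE if constant
#'   extension was used at either end).
#' @export
#' @examples
#' column_storage(c(2, 9), c(1, 1), 2, 9)   # 7 mmol m-2
column_storage <- function(depth, concentration, z_top, z_bottom) {
  check_strictly_increasing(depth, "depth")
  stop_if_not(z_bottom > z_top, "z_bottom must exceed z_top")
  inside <- depth >= z_top & depth <= z_bottom
  stop_if_not(any(inside), "no samples inside the integration bounds")
  z <- depth[inside]; c_ <- concentration[inside]
  extended <- FALSE
  if (z[1] > z_top) { z <- c(z_top, z); c_ <- c(c_[1], c_); extended <- TRUE }
  nz <- length(z)
  if (z[nz] < z_bottom) {
    z <- c(z, z_bottom); c_ <- c(c_, c_[nz]); extended <- TRUE
  }
  out <- trapz_(z, c_)
  attr(out, "extended") <- extended
  out
}

#' Percent change in areal storage between two dates
#'
#' 100 * (S2 - S1) / S1 over a common integration stratum.
#'
#' @param depth1,concentration1 first (earlier) profile.
#' @param depth2,concentration2 second (later) profile.
#' @param z_top,z_bottom common integration bounds, m.
#' @return percent change (negative = loss).
#' @export
storage_change <- function(depth1, concentration1, depth2, concentration2,
                           z_top, z_bottom) {
  s1 <- as.numeric(column_storage(depth1, concentration1, z_top, z_bottom))
  s2 <- as.numeric(column_storage(depth2, concentration2, z_top, z_bottom))
  stop_if_not(s1 != 0, "initial storage is zero")
  100 * (s2 - s1) / s1
}
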