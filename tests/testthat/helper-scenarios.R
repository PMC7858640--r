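# shared fixtures, all built in code

default_scenario <- function(seed = 421L) lake_scenario(seed = seed)

# scenario trimmed for fast EEM tests: 2 components, few samples, coarse
# emission grid handled by generate_eems() arguments
small_eem_scenario <- function(seed = 99L) {
  lake_scenario(eem_n_samples = 8,
                eem_ex_peaks = c(280, 370), eem_ex_sd = c(25, 30),
                eem_em_peaks = c(350, 470), eem_em_sd = c(30, 40),
                seed = seed)
}

# a single-exponential CDOM absorption spectrum built directly (no offset,
# already null-corrected)
exponential_absorbance <- function(a320 = 0.55, S = 0.018,
                                   pathlength = 0.10,
                                   wavelength = 200:800) {
  a <- a320 * exp(-S * (wavelength - 320))
  absorbance_spectrum(wavelength, a * pathlength / 2.303,
                      pathlength = pathlength,
                      blank_subtracted = TRUE, null_corrected = TRUE)
}

# minimal flat-spectrum irradiance profile: air record plus underwater
# records following exp(-kd * z) below an ice that transmits t_ice
flat_irradiance <- function(depths, kd = 1, t_ice = 0.5, E0 = 100,
                            wavelength = 400:409, reflectance = NULL) {
  Ed <- vapply(c(NA, depths), function(z) {
    if (is.na(z)) rep(E0, length(wavelength))
    else rep(E0 * t_ice * exp(-kd * z), length(wavelength))
  }, numeric(length(wavelength)))
  Eu <- if (!is.null(reflectance)) Ed * reflectance else NULL
  if (!is.null(Eu)) Eu[, 1] <- 0
  irradiance_profile(wavelength, c(NA, depths), Ed, Eu)
}
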