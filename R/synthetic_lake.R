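# Synthetic under-ice lake with known ground truth.
#
# The generators emulate a small, ice-covered, ultra-oligotrophic polar
# lake: a three-layer density structure (stable boundary layer under the
# ice, mid-column convective cell, stable bottom layer over the sediments),
# dilute calcium-bicarbonate salinity increasing with depth, inverse
# thermal stratification, weakly colored exponential CDOM, trilinear EEMs
# with scatter ridges, Beer-Lambert layered irradiance under a partially
# transmitting ice cover, and strongly supersaturated greenhouse-gas
# profiles. Every generator is a pure function of (scenario, stage seed),
# and every forward model is shared with the corresponding inversion so
# that parameter recovery is exact at zero noise.

#' Define a synthetic lake scenario
#'
#' All ground-truth parameters of the synthetic campaign, with defaults
#' representing a mid-summer ice-covered polar-desert lake (9.7 m deep,
#' 2 m of ice, convective cell between 4 and 8 m, temperatures below the
#' density maximum, conductance rising monotonically from 150 to 330
#' uS/cm).
#'
#' @param max_depth lake depth, m.
#' @param ice_thickness m; the water column spans ice_thickness..max_depth.
#' @param depth_step CTD depth grid step, m.
#' @param layer_bounds `c(z1, z2)`: bottom of the surface stable layer and
#'   top of the bottom stable layer, m.
#' @param T_params `c(under_ice, mid, bottom)` temperatures, degC (all
#'   must stay at or below 6.5; defaults keep the column under the density
#'   maximum so warming with depth is stabilizing).
#' @param cond_params `c(under_ice, at_z1, bottom)` specific conductance,
#'   uS/cm, non-decreasing (constant within the convective cell).
#' @param o2_sat_params `c(under_ice, cell, bottom)` oxygen saturation, %.
#' @param chl_params `c(background, bottom_peak)` chlorophyll a, ug/L.
#' @param wavelength_grid nm for irradiance (default 278:720).
#' @param kd_scale per-layer multipliers of the spectral attenuation shape.
#' @param ice_transmittance bulk spectral transmittance of the ice cover
#'   (scalar or vector over the wavelength grid).
#' @param surface_scale peak incident spectral irradiance, mW m-2 nm-1.
#' @param reflectance_true imposed E_u/E_d ratio.
#' @param irradiance_depths underwater measurement depths, m (first one at
#'   the ice bottom, the "just below ice" record).
#' @param cdom_depths CDOM/EEM sampling depths, m.
#' @param cdom_a320 true Napierian absorption at 320 nm per sample, 1/m.
#' @param cdom_S true spectral slope, 1/nm.
#' @param cdom_offset constant decadic-absorbance offset added to exercise
#'   the null-point correction.
#' @param doc DOC per CDOM sample, mg/L.
#' @param eem_n_samples number of synthetic EEM samples.
#' @param eem_ex_peaks,eem_ex_sd,eem_em_peaks,eem_em_sd Gaussian parameters
#'   (nm) of the K fluorophore loadings (K = length of the peak vectors).
#' @param eem_score_range range of the uniform true Fmax scores, Raman
#'   units.
#' @param gas_depths headspace sampling depths, m.
#' @param gas_bottom_sat named vector of bottom-water saturations (%):
#'   profile endpoints; the mid-column is homogeneous near the `gas_mid_sat`
#'   values.
#' @param gas_mid_sat named vector of mid-column saturations (%).
#' @param gas_ambient_ppm ambient air mixing ratios, ppm.
#' @param gas_summer_change named percent change of areal storage between
#'   the two synthetic sampling dates (applied as a uniform scaling).
#' @param equilibration_T headspace shaking temperature, degC.
#' @param noise named list of instrument noise levels: `ctd` and
#'   `radiometer` and `fluorometer` and `gc` are relative sd; `absorbance`
#'   is an absolute decadic-absorbance sd.
#' @param seed integer master seed; each generator draws from a stage-
#'   specific stream derived from it.
#' @return validated list of class `lake_scenario`.
#' @export
lake_scenario <- function(max_depth = 9.7,
                          ice_thickness = 2.0,
                          depth_step = 0.1,
                          layer_bounds = c(4.0, 8.0),
                          T_params = c(0.5, 3.2, 3.9),
                          cond_params = c(150, 250, 330),
                          o2_sat_params = c(100, 160, 50),
                          chl_params = c(0.5, 1.5),
                          wavelength_grid = 278:720,
                          kd_scale = c(0.50, 0.40, 0.90),
                          ice_transmittance = 0.29,
                          surface_scale = 1000,
                          reflectance_true = 0.02,
                          irradiance_depths = NULL,
                          cdom_depths = c(2.2, 4.0, 6.0, 7.8),
                          cdom_a320 = c(0.55, 0.50, 0.50, 0.60),
                          cdom_S = 0.018,
                          cdom_offset = 0.01,
                          doc = 2.0,
                          eem_n_samples = 20,
                          eem_ex_peaks = c(270, 320, 370),
                          eem_ex_sd = c(25, 30, 30),
                          eem_em_peaks = c(350, 430, 480),
                          eem_em_sd = c(25, 35, 40),
                          eem_score_range = c(0.5, 3),
                          gas_depths = seq(2, 9, by = 1),
                          gas_bottom_sat = c(CO2 = 497, CH4 = 355000,
                                             N2O = 120, O2 = 50),
                          gas_mid_sat = c(CO2 = 250, CH4 = 5000,
                                          N2O = 222, O2 = 160),
                          gas_ambient_ppm = c(CO2 = 400, CH4 = 1.9,
                                              N2O = 0.33, O2 = 209460),
                          gas_summer_change = c(CO2 = -50, CH4 = -50,
                                                N2O = -19, O2 = 32),
                          equilibration_T = 15,
                          noise = list(ctd = 0.001, radiometer = 0.02,
                                       absorbance = 5e-4,
                                       fluorometer = 0.01, gc = 0.02),
                          seed = 421L) {
  stop_if_not(max_depth > ice_thickness, "max_depth must exceed ice depth")
  stop_if_not(layer_bounds[1] > ice_thickness &&
                layer_bounds[2] > layer_bounds[1] &&
                layer_bounds[2] < max_depth,
              "layer_bounds must fall inside the water column, in order")
  stop_if_not(all(T_params <= 6.5), "temperatures must stay <= 6.5 degC")
  stop_if_not(all(diff(cond_params) >= 0),
              "conductance parameters must be non-decreasing with depth")
  check_strictly_increasing(wavelength_grid, "wavelength grid")
  stop_if_not(all(kd_scale >= 0) && length(kd_scale) == 3,
              "kd_scale must be 3 non-negative layer multipliers")
  stop_if_not(all(cdom_a320 >= 0) && cdom_S > 0,
              "cdom_a320 must be >= 0 and cdom_S > 0")
  stop_if_not(length(eem_ex_peaks) == length(eem_em_peaks) &&
                length(eem_ex_peaks) >= 1, "mismatched EEM component spec")
  stop_if_not(all(eem_score_range > 0), "EEM scores must be positive")
  stop_if_not(all(gas_bottom_sat >= 0) && all(gas_mid_sat >= 0),
              "gas saturations must be non-negative")
  if (is.null(irradiance_depths))
    irradiance_depths <- unique(c(ice_thickness,
                                  seq(ceiling(ice_thickness) + 1, max_depth,
                                      by = 1), max_depth))
  check_strictly_increasing(irradiance_depths, "irradiance depths")
  stop_if_not(irradiance_depths[1] >= ice_thickness,
              "irradiance depths must start at or below the ice bottom")
  sc <- list(max_depth = max_depth, ice_thickness = ice_thickness,
             depth_step = depth_step, layer_bounds = layer_bounds,
             T_params = T_params, cond_params = cond_params,
             o2_sat_params = o2_sat_params, chl_params = chl_params,
             wavelength_grid = wavelength_grid, kd_scale = kd_scale,
             ice_transmittance = ice_transmittance,
             surface_scale = surface_scale,
             reflectance_true = reflectance_true,
             irradiance_depths = irradiance_depths,
             cdom_depths = cdom_depths, cdom_a320 = cdom_a320,
             cdom_S = cdom_S, cdom_offset = cdom_offset, doc = doc,
             eem_n_samples = eem_n_samples, eem_ex_peaks = eem_ex_peaks,
             eem_ex_sd = eem_ex_sd, eem_em_peaks = eem_em_peaks,
             eem_em_sd = eem_em_sd, eem_score_range = eem_score_range,
             gas_depths = gas_depths, gas_bottom_sat = gas_bottom_sat,
             gas_mid_sat = gas_mid_sat, gas_ambient_ppm = gas_ambient_ppm,
             gas_summer_change = gas_summer_change,
             equilibration_T = equilibration_T,
             noise = noise, seed = as.integer(seed))
  class(sc) <- "lake_scenario"
  sc
}

#' @export
print.lake_scenario <- function(x, ...) {
  cat("lake_scenario:", x$max_depth, "m deep under", x$ice_thickness,
      "m of ice; convective cell", x$layer_bounds[1], "-",
      x$layer_bounds[2], "m;", length(x$eem_ex_peaks),
      "EEM components; seed", x$seed, "\n")
  invisible(x)
}

# stage-specific RNG streams derived from the master seed; offsets are
# arbitrary fixed constants, kept < 2^31 - seed
.stage_seed <- function(scenario, stage) {
  offs <- c(ctd = 101L, irradiance = 202L, cdom = 303L, eem = 404L,
            gas = 505L)
  scenario$seed + offs[[stage]]
}

.in_layer <- function(z, scenario) {
  findInterval(z, c(scenario$ice_thickness, scenario$layer_bounds,
                    scenario$max_depth), rightmost.closed = TRUE)
}

# piecewise-linear profile through the three layers:
# v1 at ice bottom -> v2 at layer bound 1, constant v2 across the cell,
# v2 -> v3 across the bottom layer
.three_layer <- function(z, scenario, v1, v2, v3) {
  b <- scenario$layer_bounds
  ifelse(z <= b[1],
         v1 + (v2 - v1) * (z - scenario$ice_thickness) /
           (b[1] - scenario$ice_thickness),
         ifelse(z <= b[2], v2,
                v2 + (v3 - v2) * (z - b[2]) / (scenario$max_depth - b[2])))
}

#' True CTD profiles of the scenario (no noise)
#'
#' @param scenario a [lake_scenario()].
#' @return data.frame with `depth`, `temperature`, `conductance`,
#'   `oxygen_sat`, `chl_a`.
#' @export
true_ctd <- function(scenario) {
  z <- seq(scenario$ice_thickness, scenario$max_depth,
           by = scenario$depth_step)
  b <- scenario$layer_bounds
  chl <- ifelse(z <= b[2], scenario$chl_params[1],
                scenario$chl_params[1] +
                  (scenario$chl_params[2] - scenario$chl_params[1]) *
                  (z - b[2]) / (scenario$max_depth - b[2]))
  data.frame(
    depth = z,
    temperature = .three_layer(z, scenario, scenario$T_params[1],
                               scenario$T_params[2], scenario$T_params[3]),
    conductance = .three_layer(z, scenario, scenario$cond_params[1],
                               scenario$cond_params[2],
                               scenario$cond_params[3]),
    oxygen_sat = .three_layer(z, scenario, scenario$o2_sat_params[1],
                              scenario$o2_sat_params[2],
                              scenario$o2_sat_params[3]),
    chl_a = chl
  )
}

#' Generate noisy CTD profiles
#'
#' True profiles ([true_ctd()]) plus additive Gaussian noise with the
#' scenario's relative CTD sd. Identical (scenario, seed) gives identical
#' output.
#'
#' @param scenario a [lake_scenario()].
#' @param noise_sd relative noise sd; default the scenario's `noise$ctd`.
#' @return data.frame as [true_ctd()].
#' @export
generate_ctd <- function(scenario, noise_sd = scenario$noise$ctd) {
  tr <- true_ctd(scenario)
  if (noise_sd == 0) return(tr)
  withr::with_seed(.stage_seed(scenario, "ctd"), {
    for (v in c("temperature", "conductance", "oxygen_sat", "chl_a")) {
      scale <- mean(abs(tr[[v]]))
      tr[[v]] <- tr[[v]] + stats::rnorm(nrow(tr), 0, noise_sd * scale)
    }
  })
  tr
}

# spectral shape of the water-column attenuation: CDOM-like exponential
# rise in the UV plus a red tail; multiplied per layer by kd_scale
.kd_shape <- function(wl) {
  0.15 + 1.2 * exp(-0.010 * (wl - 278)) +
    0.8 * pmax((wl - 500) / 220, 0)^4
}

#' True layered spectral attenuation coefficients
#'
#' @param scenario a [lake_scenario()].
#' @return matrix wavelength x 3 layers of K_d (1/m), all non-negative.
#' @export
true_kd <- function(scenario) {
  shape <- .kd_shape(scenario$wavelength_grid)
  kd <- outer(shape, scenario$kd_scale)
  colnames(kd) <- c("surface_stable", "convective", "bottom_stable")
  kd
}

# daylight-like incident spectrum peaking near 500 nm
.surface_spectrum <- function(wl, scale) {
  scale * exp(-((wl - 500) / 150)^2)
}

#' Generate a spectral irradiance profile by layered Beer-Lambert transfer
#'
#' E_d(lambda, z) = E_air(lambda) * T_ice(lambda) *
#' exp(-integral of kd_true over the water path), integrated piecewise
#' across the three layers; E_u = R * E_d with the scenario's imposed
#' reflectance. Includes the in-air incident record; the first underwater
#' record sits at the ice bottom (the "just below ice" measurement).
#'
#' @param scenario a [lake_scenario()].
#' @param noise_sd relative radiometer noise; default from the scenario.
#' @return an [irradiance_profile()].
#' @export
generate_irradiance <- function(scenario,
                                noise_sd = scenario$noise$radiometer) {
  wl <- scenario$wavelength_grid
  kd <- true_kd(scenario)
  stop_if_not(all(kd >= 0), "negative kd_true")
  E_air <- .surface_spectrum(wl, scenario$surface_scale)
  t_ice <- rep(scenario$ice_transmittance, length.out = length(wl))
  edges <- c(scenario$ice_thickness, scenario$layer_bounds,
             scenario$max_depth)
  optical_depth <- function(z) {
    # per-wavelength integral of kd from the ice bottom down to z
    tau <- numeric(length(wl))
    for (l in 1:3) {
      dz <- max(0, min(z, edges[l + 1]) - edges[l])
      if (dz > 0) tau <- tau + kd[, l] * dz
    }
    tau
  }
  zs <- scenario$irradiance_depths
  Ed_uw <- vapply(zs, function(z) E_air * t_ice * exp(-optical_depth(z)),
                  numeric(length(wl)))
  Ed <- cbind(E_air, Ed_uw)
  Eu <- cbind(0, scenario$reflectance_true * Ed_uw)
  if (noise_sd > 0) {
    withr::with_seed(.stage_seed(scenario, "irradiance"), {
      Ed <- pmax(Ed * (1 + matrix(stats::rnorm(length(Ed), 0, noise_sd),
                                  nrow(Ed))), 0)
      Eu <- pmax(Eu * (1 + matrix(stats::rnorm(length(Eu), 0, noise_sd),
                                  nrow(Eu))), 0)
    })
  }
  labels <- c("air", "JBI", format(zs[-1], trim = TRUE))
  irradiance_profile(wl, c(NA, zs), Ed, Eu, labels = labels)
}

#' Generate CDOM absorbance spectra with known exponential truth
#'
#' Decadic absorbance A(lambda) = a320 * exp(-S (lambda - 320)) * L / 2.303
#' plus the scenario's constant offset (exercising the null-point
#' correction) and spectrophotometer noise.
#'
#' @param scenario a [lake_scenario()].
#' @param wavelength output grid, nm (default 200-800 at 1 nm).
#' @param pathlength cuvette length, m.
#' @param noise_sd absolute absorbance noise sd; default from scenario.
#' @return list of [absorbance_spectrum()] objects, one per `cdom_depths`
#'   entry ... each carries attributes `true_a320`, `true_S`, `depth`.
#' @export
generate_cdom_spectra <- function(scenario, wavelength = 200:800,
                                  pathlength = 0.10,
                                  noise_sd = scenario$noise$absorbance) {
  specs <- vector("list", length(scenario$cdom_depths))
  noise_mat <- if (noise_sd > 0)
    withr::with_seed(.stage_seed(scenario, "cdom"),
                     matrix(stats::rnorm(length(wavelength) * length(specs),
                                         0, noise_sd),
                            ncol = length(specs)))
  else matrix(0, length(wavelength), length(specs))
  for (i in seq_along(specs)) {
    a_true <- scenario$cdom_a320[i] *
      exp(-scenario$cdom_S * (wavelength - 320))
    A <- a_true * pathlength / 2.303 + scenario$cdom_offset + noise_mat[, i]
    sp <- absorbance_spectrum(wavelength, A, pathlength = pathlength,
                              blank_subtracted = TRUE)
    attr(sp, "true_a320") <- scenario$cdom_a320[i]
    attr(sp, "true_S") <- scenario$cdom_S
    attr(sp, "depth") <- scenario$cdom_depths[i]
    specs[[i]] <- sp
  }
  specs
}

# unimodal Gaussian loading on a grid, peak-normalized to 1
.gauss_loading <- function(grid, peak, sd) {
  v <- exp(-((grid - peak) / sd)^2 / 2)
  v / max(v)
}

#' Generate a synthetic EEM set with trilinear truth plus scatter
#'
#' Each sample EEM is sum_k score_k * em_loading_k x ex_loading_k with
#' Gaussian unimodal loadings (peak-normalized, so true scores are Fmax
#' values), plus first- and second-order Rayleigh and water-Raman scatter
#' ridges, plus fluorometer noise. Companion absorbance spectra are
#' attached for inner-filter testing.
#'
#' @param scenario a [lake_scenario()].
#' @param ex,em measurement grids, nm.
#' @param scatter add scatter ridges? (TRUE by default).
#' @param noise_sd relative noise (of the max signal); default from
#'   scenario.
#' @return list with `eems` (list of [eem()]), `truth` (list with `scores`,
#'   `em_loadings`, `ex_loadings`), `absorbance` (companion spectra) and
#'   `scatter` (logical).
#' @export
generate_eems <- function(scenario, ex = seq(250, 450, by = 10),
                          em = seq(300, 560, by = 2), scatter = TRUE,
                          noise_sd = scenario$noise$fluorometer) {
  K <- length(scenario$eem_ex_peaks)
  exL <- vapply(seq_len(K), function(k)
    .gauss_loading(ex, scenario$eem_ex_peaks[k], scenario$eem_ex_sd[k]),
    numeric(length(ex)))
  emL <- vapply(seq_len(K), function(k)
    .gauss_loading(em, scenario$eem_em_peaks[k], scenario$eem_em_sd[k]),
    numeric(length(em)))
  stop_if_not(all(exL >= 0) && all(emL >= 0), "negative loadings")
  n <- scenario$eem_n_samples
  res <- withr::with_seed(.stage_seed(scenario, "eem"), {
    scores <- matrix(stats::runif(n * K, scenario$eem_score_range[1],
                                  scenario$eem_score_range[2]), n, K)
    eems <- vector("list", n)
    peak <- max(scores)
    em_g <- matrix(em, length(em), length(ex))
    ex_g <- matrix(ex, length(em), length(ex), byrow = TRUE)
    ridge <- function(centre, width, amp)
      amp * exp(-((em_g - centre) / width)^2 / 2)
    for (i in seq_len(n)) {
      M <- emL %*% (scores[i, ] * t(exL))
      if (scatter)
        M <- M + ridge(ex_g, 8, 5 * peak) + ridge(2 * ex_g, 8, peak) +
          ridge(raman_emission(ex_g), 4, 0.5 * peak)
      if (noise_sd > 0)
        M <- M + matrix(stats::rnorm(length(M), 0, noise_sd * peak),
                        nrow(M))
      eems[[i]] <- eem(ex, em, M,
                       corrections = c("blank", "inner_filter"))
    }
    list(scores = scores, eems = eems)
  })
  # companion absorbance spectra (low CDOM; recycled over samples)
  wl_abs <- 200:800
  absorb <- lapply(seq_len(n), function(i) {
    a320 <- scenario$cdom_a320[((i - 1) %% length(scenario$cdom_a320)) + 1]
    A <- a320 * exp(-scenario$cdom_S * (wl_abs - 320)) * 0.10 / 2.303
    absorbance_spectrum(wl_abs, A, pathlength = 0.10,
                        blank_subtracted = TRUE, null_corrected = TRUE)
  })
  # water blank carrying only the Raman ridge, scaled to unit peak area so
  # Raman normalization is exercised without changing the truth scale
  em_g <- matrix(em, length(em), length(ex))
  ex_g <- matrix(ex, length(em), length(ex), byrow = TRUE)
  blank_int <- exp(-((em_g - raman_emission(ex_g)) / 4)^2 / 2)
  blank <- eem(ex, em, blank_int)
  blank$intensity <- blank$intensity / raman_area(blank)
  list(eems = res$eems,
       truth = list(scores = res$scores, em_loadings = emL,
                    ex_loadings = exL),
       absorbance = absorb,
       blank = blank,
       scatter = scatter)
}

#' True dissolved-gas concentration profiles
#'
#' Saturation profiles follow the three-layer structure (near-ambient under
#' the ice for CO2/O2, homogeneous mid-column, diverging toward the bottom)
#' and are converted to concentrations (umol/L) at the in-situ temperature.
#' The second sampling date scales each gas by the scenario's
#' `gas_summer_change`.
#'
#' @param scenario a [lake_scenario()].
#' @param date `"june"` or `"july"`.
#' @return data.frame with `gas`, `depth`, `in_situ_T`, `saturation`,
#'   `concentration` (umol/L).
#' @export
true_gas_profiles <- function(scenario, date = c("june", "july")) {
  date <- match.arg(date)
  z <- scenario$gas_depths
  ctd <- true_ctd(scenario)
  Tz <- stats::approx(ctd$depth, ctd$temperature, xout = z, rule = 2)$y
  out <- list()
  for (g in names(scenario$gas_mid_sat)) {
    sat <- .three_layer(z, scenario,
                        v1 = if (g %in% c("CO2", "O2")) 110 else
                          scenario$gas_mid_sat[[g]] * 0.8,
                        v2 = scenario$gas_mid_sat[[g]],
                        v3 = scenario$gas_bottom_sat[[g]])
    if (date == "july")
      sat <- sat * (1 + scenario$gas_summer_change[[g]] / 100)
    K0 <- gas_solubility(g, Tz)
    C_eq <- K0 * scenario$gas_ambient_ppm[[g]] * 1e-6 * 1e6   # umol/L
    out[[g]] <- data.frame(gas = g, depth = z, in_situ_T = Tz,
                           saturation = sat,
                           concentration = sat / 100 * C_eq)
  }
  do.call(rbind, out)
}

#' Generate headspace equilibration records from the gas truth
#'
#' Applies the exact forward mass-balance model ([headspace_forward()]) to
#' the true concentrations of CO2, CH4 and N2O, then adds relative GC
#' noise on the measured mixing ratio. O2 is a sensor variable and gets no
#' bottle record.
#'
#' @param scenario a [lake_scenario()].
#' @param date `"june"` or `"july"`.
#' @param noise_sd relative GC noise; default from the scenario.
#' @return a [headspace_sample()] data.frame (one row per gas x depth) with
#'   the true concentration attached as `true_concentration`.
#' @export
generate_headspace <- function(scenario, date = "june",
                               noise_sd = scenario$noise$gc) {
  tg <- true_gas_profiles(scenario, date)
  tg <- tg[tg$gas %in% c("CO2", "CH4", "N2O"), ]
  x <- mapply(function(conc, g)
    headspace_forward(conc, g,
                      ambient_ppm = scenario$gas_ambient_ppm[[g]],
                      equilibration_T = scenario$equilibration_T),
    tg$concentration, tg$gas)
  if (noise_sd > 0)
    x <- withr::with_seed(.stage_seed(scenario, "gas") +
                            (date == "july"),
                          pmax(x * (1 + stats::rnorm(length(x), 0,
                                                     noise_sd)), 0))
  out <- headspace_sample(gas = tg$gas, depth = tg$depth,
                          measured_ppm = x,
                          ambient_ppm = unname(
                            scenario$gas_ambient_ppm[tg$gas]),
                          equilibration_T = scenario$equilibration_T,
                          in_situ_T = tg$in_situ_T)
  out$true_concentration <- tg$concentration
  out
}
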