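#' Default major-ion template for a calcium-bicarbonate freshwater lake
#'
#' Mass fractions of the major ions, their equivalent weights (g per
#' equivalent) and limiting equivalent conductances at 25 degC
#' (S cm2 per equivalent). The default composition is dominated by Ca2+ and
#' HCO3-, the typical solute mixture of polar-desert lakes on carbonate
#' terrain; any template with fractions summing to 1 may be substituted.
#'
#' @return A data.frame with columns `ion`, `fraction`, `eq_weight`,
#'   `eq_conductance`.
#' @export
#' @examples
#' default_ion_template()
default_ion_template <- function() {
  data.frame(
    ion            = c("Ca", "Mg", "Na", "K", "HCO3", "SO4", "Cl"),
    fraction       = c(0.20, 0.03, 0.02, 0.01, 0.55, 0.15, 0.04),
    eq_weight      = c(20.04, 12.15, 22.99, 39.10, 61.02, 48.03, 35.45),
    eq_conductance = c(59.5, 53.1, 50.1, 73.5, 44.5, 80.0, 76.3),
    stringsAsFactors = FALSE
  )
}

#' Salinity conversion factor from an ion template
#'
#' Computes the linear factor k (g/kg per uS/cm) that maps specific
#' conductance at 25 degC to a salinity proxy, from the equivalent
#' conductances of the template ions: 1 g/L of dissolved salt with mass
#' fractions f_i contributes `sum(1000 * f_i / EW_i * lambda_i)` uS/cm, and
#' k is the reciprocal of that sum.
#'
#' @param template ion template as returned by [default_ion_template()].
#' @return k in g/kg per uS/cm.
#' @export
salinity_factor <- function(template = default_ion_template()) {
  stop_if_not(all(c("fraction", "eq_weight", "eq_conductance") %in%
                    names(template)),
              "template must have fraction, eq_weight, eq_conductance")
  stop_if_not(abs(sum(template$fraction) - 1) < 1e-6,
              "ion mass fractions must sum to 1")
  cond_per_g <- sum(1000 * template$fraction / template$eq_weight *
                      template$eq_conductance)
  1 / cond_per_g
}

#' Convert specific conductance to a salinity proxy
#'
#' Linear mapping salinity = k * C25 with k derived from the major-ion
#' composition ([salinity_factor()]). Designed for dilute freshwater, where
#' the practical salinity scale (built for seawater ion ratios) does not
#' apply.
#'
#' @param conductance specific conductance at 25 degC, uS/cm; must be >= 0.
#' @param template ion template (see [default_ion_template()]).
#' @return salinity proxy in g/kg, same length as `conductance`.
#' @export
#' @examples
#' conductivity_to_salinity(300)
conductivity_to_salinity <- function(conductance,
                                     template = default_ion_template()) {
  stop_if_not(all(is.finite(conductance)) && all(conductance >= 0),
              "conductance must be finite and >= 0")
  salinity_factor(template) * conductance
}

#' Freshwater density from temperature and salinity
#'
#' Limnological equation of state: a sixth-order pure-water polynomial in
#' temperature (density maximum near 3.98 degC) plus a linear haline
#' contraction term appropriate for dilute lake water. Coefficients follow
#' the Chen-Millero freshwater formulation at surface pressure; no pressure
#' term is included (intended for shallow lakes).
#'
#' @param temperature degC, in \[-2, 40\].
#' @param salinity g/kg, >= 0 (expected < 1 for freshwater).
#' @return density in kg/m3.
#' @export
#' @examples
#' water_density(4, 0)    # 999.972 kg/m3
water_density <- function(temperature, salinity = 0) {
  stop_if_not(all(is.finite(temperature)),
              "temperature must be finite")
  if (any(temperature < -2 | temperature > 40))
    stop("temperature out of supported range [-2, 40] degC", call. = FALSE)
  stop_if_not(all(is.finite(salinity)) && all(salinity >= 0),
              "salinity must be finite and >= 0")
  t <- temperature
  rho0 <- 999.8395 + 6.7914e-2 * t - 9.0894e-3 * t^2 + 1.0171e-4 * t^3 -
    1.2846e-6 * t^4 + 1.1592e-8 * t^5 - 5.0125e-11 * t^6
  haline <- 0.8181 - 3.85e-3 * t + 4.96e-5 * t^2
  rho0 + haline * salinity
}

#' Density profile from CTD temperature and conductivity
#'
#' @param depth m, strictly increasing.
#' @param temperature degC at each depth.
#' @param conductance specific conductance at 25 degC (uS/cm) at each depth;
#'   `NULL` for a temperature-only profile.
#' @param template ion template for the salinity conversion.
#' @return data.frame with `depth`, `rho_T` (temperature-only density),
#'   `rho_TC` (temperature + salinity) and `salinity_proxy` (g/kg).
#' @export
density_profile <- function(depth, temperature, conductance = NULL,
                            template = default_ion_template()) {
  check_strictly_increasing(depth, "depth")
  stop_if_not(length(temperature) == length(depth),
              "temperature and depth lengths differ")
  sal <- if (is.null(conductance)) rep(0, length(depth)) else {
    stop_if_not(length(conductance) == length(depth),
                "conductance and depth lengths differ")
    conductivity_to_salinity(conductance, template)
  }
  data.frame(depth = depth,
             rho_T = water_density(temperature, 0),
             rho_TC = water_density(temperature, sal),
             salinity_proxy = sal)
}

#' Brunt-Vaisala (buoyancy) frequency from a density profile
#'
#' For each adjacent depth pair, N2 = g * (d rho / d z) / rho_bar with
#' g = 9.8 m/s2 and rho_bar fixed at the maximum density of pure water
#' (1000 kg/m3). N2 is reported signed: negative values mark convectively
#' unstable strata and are never clamped. N = sqrt(N2) where N2 >= 0 and NA
#' (flagged) otherwise. Values are assigned to pair midpoints.
#'
#' @param depth m, strictly increasing, length >= 2.
#' @param rho density (kg/m3) at each depth; typically `rho_TC` from
#'   [density_profile()].
#' @param g gravitational acceleration, m/s2.
#' @param rho_bar reference density, kg/m3.
#' @return data.frame with `depth_mid`, `N2` (1/s2), `N` (1/s, NA where
#'   N2 < 0) and `stable` (logical, N2 >= 0).
#' @export
#' @examples
#' bv <- brunt_vaisala(c(0, 1), c(1000, 1000.1))
#' bv$N2   # 9.8e-4
brunt_vaisala <- function(depth, rho, g = 9.8, rho_bar = 1000) {
  check_strictly_increasing(depth, "depth")
  stop_if_not(length(depth) >= 2, "need at least 2 depths")
  stop_if_not(length(rho) == length(depth), "rho and depth lengths differ")
  dz <- diff(depth)
  if (any(dz == 0)) stop("zero depth spacing", call. = FALSE)
  N2 <- g * (diff(rho) / dz) / rho_bar
  data.frame(depth_mid = depth[-length(depth)] + dz / 2,
             N2 = N2,
             N = ifelse(N2 >= 0, sqrt(pmax(N2, 0)), NA_real_),
             stable = N2 >= 0)
}

#' Detect the three-layer stratification structure of an ice-covered lake
#'
#' Labels the contiguous run of segments with N2 >= threshold at the top of
#' the profile as the surface stable (boundary) layer, the run at the bottom
#' as the bottom stable layer, and the enclosed run as the convective cell.
#' The canonical under-ice structure is stable/convective/stable; if the
#' profile does not show it, `resolved` is FALSE and the degenerate layout
#' is described in `note`.
#'
#' @param stability data.frame from [brunt_vaisala()].
#' @param threshold_N2 stability threshold, 1/s2.
#' @return list with `resolved` (logical), `surface`, `convective`, `bottom`
#'   (each a depth interval c(top, bottom) in m or NULL), `labels` (per
#'   segment) and `note`.
#' @export
detect_layers <- function(stability, threshold_N2 = 5e-5) {
  stop_if_not(is.data.frame(stability) &&
                all(c("depth_mid", "N2") %in% names(stability)),
              "stability must come from brunt_vaisala()")
  n <- nrow(stability)
  if (n < 3)
    return(list(resolved = FALSE, surface = NULL, convective = NULL,
                bottom = NULL, labels = rep(NA_character_, n),
                note = "structure not resolvable: fewer than 3 segments"))
  stab <- stability$N2 >= threshold_N2
  z <- stability$depth_mid
  # segment edges recovered from midpoints (exact for the uniform grids the
  # profiler produces; approximate otherwise)
  inner <- (z[-n] + z[-1]) / 2
  edges <- c(z[1] - (z[2] - z[1]) / 2, inner, z[n] + (z[n] - z[n - 1]) / 2)
  span <- c(edges[1], edges[n + 1])
  if (!any(stab))
    return(list(resolved = FALSE, surface = NULL,
                convective = span, bottom = NULL,
                labels = rep("convective", n),
                note = "all segments below threshold: single convective layer"))
  if (all(stab))
    return(list(resolved = FALSE, surface = span, convective = NULL,
                bottom = NULL, labels = rep("surface_stable", n),
                note = "all segments stable: no convective layer"))
  top_run <- which.min(stab) - 1            # stable segments before first unstable
  bot_run <- which.min(rev(stab)) - 1       # stable segments after last unstable
  if (top_run == 0 || bot_run == 0)
    return(list(resolved = FALSE, surface = NULL, convective = NULL,
                bottom = NULL, labels = rep(NA_character_, n),
                note = "no stable boundary layer at one end"))
  mid_idx <- seq(top_run + 1, n - bot_run)
  if (any(stab[mid_idx])) {
    note <- "interior stable segments folded into convective cell"
  } else note <- "canonical three-layer structure"
  labels <- rep("convective", n)
  labels[seq_len(top_run)] <- "surface_stable"
  labels[seq(n - bot_run + 1, n)] <- "bottom_stable"
  list(resolved = TRUE,
       surface = c(span[1], edges[top_run + 1]),
       convective = c(edges[top_run + 1], edges[n - bot_run + 1]),
       bottom = c(edges[n - bot_run + 1], span[2]),
       labels = labels,
       note = note)
}
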