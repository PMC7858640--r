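# Spectral irradiance profiles and apparent optical properties.
#
# An irradiance_profile stores E_d (and optionally E_u) on a wavelength x
# depth grid. One record is the incident reference measured in air above the
# surface; underwater records are keyed by depth in m below the ice surface.
# The record just below the ice (JBI) is an ordinary underwater record; the
# air -> JBI attenuation pair is flagged "apparent" because it folds in
# reflection losses at the ice surface.

#' Construct a spectral irradiance profile
#'
#' @param wavelength nm, uniform strictly increasing grid (typically 278-720
#'   at 1 nm).
#' @param depth numeric depth (m) of each underwater record; use `NA` for
#'   the single in-air incident record.
#' @param Ed matrix of downwelling irradiance, mW m-2 nm-1, dimensions
#'   `length(wavelength)` x `length(depth)`; all values >= 0.
#' @param Eu optional matrix of upwelling irradiance, same shape.
#' @param labels optional character labels per record (e.g. "air", "JBI",
#'   "3.0"). Defaults are generated.
#' @return object of class `irradiance_profile`.
#' @export
irradiance_profile <- function(wavelength, depth, Ed, Eu = NULL,
                               labels = NULL) {
  check_strictly_increasing(wavelength, "wavelength")
  if (length(wavelength) > 2) {
    steps <- diff(wavelength)
    stop_if_not(max(abs(steps - steps[1])) < 1e-9,
                "wavelength grid must be uniform")
  }
  Ed <- as.matrix(Ed)
  stop_if_not(nrow(Ed) == length(wavelength) && ncol(Ed) == length(depth),
              "Ed must be wavelength x depth")
  stop_if_not(all(Ed >= 0), "Ed must be non-negative")
  n_air <- sum(is.na(depth))
  stop_if_not(n_air <= 1, "at most one in-air (NA-depth) record allowed")
  uw <- depth[!is.na(depth)]
  if (length(uw) > 0) check_strictly_increasing(uw, "underwater depth")
  if (!is.null(Eu)) {
    Eu <- as.matrix(Eu)
    stop_if_not(all(dim(Eu) == dim(Ed)), "Eu must match Ed dimensions")
  }
  if (is.null(labels))
    labels <- ifelse(is.na(depth), "air", format(depth, trim = TRUE))
  structure(list(wavelength = wavelength, depth = depth, Ed = Ed, Eu = Eu,
                 labels = labels),
            class = "irradiance_profile")
}

#' @export
print.irradiance_profile <- function(x, ...) {
  cat("irradiance_profile:", length(x$wavelength), "wavelengths (",
      min(x$wavelength), "-", max(x$wavelength), "nm ),",
      ncol(x$Ed), "records (", paste(x$labels, collapse = ", "), ")\n")
  if (!is.null(x$Eu)) cat("  upwelling irradiance present\n")
  invisible(x)
}

.profile_col <- function(profile, depth) {
  if (is.character(depth)) {
    j <- match(depth, profile$labels)
    stop_if_not(!is.na(j), sprintf("no record labelled '%s'", depth))
  } else if (is.na(depth)) {
    j <- which(is.na(profile$depth))
    stop_if_not(length(j) == 1, "no in-air record in profile")
  } else {
    j <- which(!is.na(profile$depth) &
                 abs(profile$depth - depth) < 1e-9)
    stop_if_not(length(j) == 1, sprintf("no record at depth %g m", depth))
  }
  j
}

# wavelengths where the reference irradiance is below floor_frac of its
# maximum are masked (NA) rather than divided into
.mask_floor <- function(num, den, floor_frac = 1e-6) {
  floor_v <- floor_frac * max(den, 0)
  out <- ifelse(den > floor_v, num / den, NA_real_)
  out
}

#' Spectral transmittance relative to incident irradiance in air
#'
#' T(lambda, z) = E_d(lambda, z) / E_d(lambda, air). Wavelengths where the
#' incident irradiance is below a floor (default 1e-6 of its maximum) are
#' masked as NA instead of divided.
#'
#' @param profile an [irradiance_profile()] containing an in-air record.
#' @param depth depth in m (or a record label) at which to evaluate.
#' @param floor_frac division floor as a fraction of max incident E_d.
#' @return numeric vector over the wavelength grid (fraction, not percent).
#' @export
transmittance <- function(profile, depth, floor_frac = 1e-6) {
  j_air <- .profile_col(profile, NA)
  j <- .profile_col(profile, depth)
  .mask_floor(profile$Ed[, j], profile$Ed[, j_air], floor_frac)
}

#' Spectral reflectance (upwelling / downwelling ratio) at one depth
#'
#' R(lambda, z) = E_u(lambda, z) / E_d(lambda, z), masked where E_d is below
#' the floor.
#'
#' @inheritParams transmittance
#' @return numeric vector over the wavelength grid.
#' @export
reflectance <- function(profile, depth, floor_frac = 1e-6) {
  stop_if_not(!is.null(profile$Eu), "profile has no upwelling irradiance")
  j <- .profile_col(profile, depth)
  .mask_floor(profile$Eu[, j], profile$Ed[, j], floor_frac)
}

# named band limits in nm; UVR excludes 400 nm, which belongs to PAR, so the
# two bands partition the grid without double counting
.band_limits <- function(band, wavelength) {
  if (is.character(band)) {
    band <- match.arg(toupper(band), c("TOTAL", "PAR", "UVR"))
    lim <- switch(band, TOTAL = c(278, 720), PAR = c(400, 700),
                  UVR = c(278, 399))
  } else {
    stop_if_not(is.numeric(band) && length(band) == 2 && band[1] <= band[2],
                "band must be a name or c(lo, hi)")
    lim <- band
  }
  stop_if_not(lim[1] >= min(wavelength) && lim[2] <= max(wavelength),
              "band outside the measured wavelength grid")
  lim
}

#' Band-integrated energy at one depth
#'
#' Total energy over a wavelength band as the discrete sum of spectral
#' irradiance over the 1 nm grid (a sum, not a trapezoid, matching how
#' broadband energy is reported for these profiles). Named bands: TOTAL =
#' 278-720 nm, PAR = 400-700 nm, UVR = 278-399 nm (400 nm is assigned to
#' PAR so UVR + PAR do not double count).
#'
#' @inheritParams transmittance
#' @param band `"TOTAL"`, `"PAR"`, `"UVR"` or a numeric `c(lo, hi)` in nm.
#' @return energy in mW m-2.
#' @export
band_energy <- function(profile, depth, band = "TOTAL") {
  lim <- .band_limits(band, profile$wavelength)
  j <- .profile_col(profile, depth)
  sel <- profile$wavelength >= lim[1] & profile$wavelength <= lim[2]
  sum(profile$Ed[sel, j])
}

#' Spectral diffuse attenuation coefficients between adjacent records
#'
#' For each adjacent pair of records (air and underwater, ordered air first,
#' then increasing depth), K_d(lambda) = -ln(E2/E1) / (z2 - z1) with E1
#' measured above (z1) and E2 below (z2). Values are assigned to the lower
#' depth z2. The air -> first-underwater pair is flagged `apparent` (it
#' includes reflection at the ice surface and is not a water-column
#' property); its z1 is taken as 0 m. Wavelengths where either irradiance is
#' at or below the floor are masked.
#'
#' @param profile an [irradiance_profile()] with >= 2 underwater records (an
#'   air record is optional and contributes the apparent pair).
#' @param floor_frac division floor as fraction of each spectrum's maximum.
#' @return data.frame with `wavelength`, `K_d` (1/m), `z_assigned` (m),
#'   `pair` (label "z1->z2") and `apparent` (logical).
#' @export
kd_profile <- function(profile, floor_frac = 1e-6) {
  has_air <- any(is.na(profile$depth))
  ord <- order(is.na(profile$depth), decreasing = TRUE)  # air first
  uw_idx <- which(!is.na(profile$depth))
  stop_if_not(length(uw_idx) >= 2 || (has_air && length(uw_idx) >= 1),
              "need at least two records to form a pair")
  cols <- c(if (has_air) which(is.na(profile$depth)), uw_idx)
  zs <- ifelse(is.na(profile$depth[cols]), 0, profile$depth[cols])
  out <- vector("list", length(cols) - 1)
  for (i in seq_len(length(cols) - 1)) {
    j1 <- cols[i]; j2 <- cols[i + 1]
    dz <- zs[i + 1] - zs[i]
    if (dz <= 0) stop("z2 must exceed z1 for each pair", call. = FALSE)
    E1 <- profile$Ed[, j1]; E2 <- profile$Ed[, j2]
    f1 <- floor_frac * max(E1, 0); f2 <- floor_frac * max(E2, 0)
    ok <- E1 > f1 & E2 > f2
    kd <- rep(NA_real_, length(E1))
    kd[ok] <- -log(E2[ok] / E1[ok]) / dz
    out[[i]] <- data.frame(
      wavelength = profile$wavelength,
      K_d = kd,
      z_assigned = zs[i + 1],
      pair = paste0(profile$labels[j1], "->", profile$labels[j2]),
      apparent = has_air && i == 1
    )
  }
  do.call(rbind, out)
}

#' Band-averaged diffuse attenuation coefficients
#'
#' Broadband K_d computed from band-integrated energies (not the mean of
#' spectral K_d): K_d,band = -ln(Eband2/Eband1) / (z2 - z1). This matches
#' the convention behind reported broadband PAR attenuation coefficients.
#'
#' @inheritParams kd_profile
#' @param band band name or numeric range, as in [band_energy()].
#' @return data.frame with `band`, `K_d`, `z_assigned`, `pair`, `apparent`.
#' @export
kd_band <- function(profile, band = "PAR") {
  has_air <- any(is.na(profile$depth))
  uw_idx <- which(!is.na(profile$depth))
  cols <- c(if (has_air) which(is.na(profile$depth)), uw_idx)
  zs <- ifelse(is.na(profile$depth[cols]), 0, profile$depth[cols])
  stop_if_not(length(cols) >= 2, "need at least two records")
  res <- vector("list", length(cols) - 1)
  band_name <- if (is.character(band)) band else
    paste0(band[1], "-", band[2])
  for (i in seq_len(length(cols) - 1)) {
    lab1 <- profile$labels[cols[i]]; lab2 <- profile$labels[cols[i + 1]]
    E1 <- band_energy(profile, lab1, band)
    E2 <- band_energy(profile, lab2, band)
    dz <- zs[i + 1] - zs[i]
    stop_if_not(dz > 0, "z2 must exceed z1")
    res[[i]] <- data.frame(
      band = band_name,
      K_d = if (E1 > 0 && E2 > 0) -log(E2 / E1) / dz else NA_real_,
      z_assigned = zs[i + 1],
      pair = paste0(lab1, "->", lab2),
      apparent = has_air && i == 1
    )
  }
  do.call(rbind, res)
}
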