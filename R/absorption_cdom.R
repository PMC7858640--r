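# CDOM absorbance processing, spectral indices and the absorption budget.
#
# Conventions (kept explicit because the field literature mixes them):
#   * spectrophotometer output A is DECADIC absorbance (dimensionless);
#   * absorption coefficients a are NAPIERIAN, a = 2.303 * A / L (1/m);
#   * SUVA254 uses decadic absorbance per metre divided by DOC (L mg-1 m-1);
#   * a320 and a*_CDOM use the Napierian spectrum.

#' Construct a CDOM absorbance spectrum
#'
#' @param wavelength nm, strictly increasing (typically 200-800 at 1 nm).
#' @param A decadic absorbance through the cuvette (dimensionless).
#' @param pathlength cuvette length in m (default 0.10, a 10 cm cuvette).
#' @param blank_subtracted has the blank spectrum been subtracted?
#' @param null_corrected has the null-point correction been applied?
#' @return object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelength, A, pathlength = 0.10,
                                blank_subtracted = TRUE,
                                null_corrected = FALSE) {
  check_strictly_increasing(wavelength, "wavelength")
  stop_if_not(length(A) == length(wavelength), "A and wavelength differ")
  stop_if_not(is.numeric(pathlength) && pathlength > 0,
              "pathlength must be > 0")
  structure(list(wavelength = wavelength, A = A, pathlength = pathlength,
                 blank_subtracted = isTRUE(blank_subtracted),
                 null_corrected = isTRUE(null_corrected)),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat("absorbance_spectrum:", length(x$wavelength), "points (",
      min(x$wavelength), "-", max(x$wavelength), "nm ), pathlength",
      x$pathlength, "m;",
      if (x$null_corrected) "null-corrected" else "not null-corrected", "\n")
  invisible(x)
}

#' Null-point correction of an absorbance spectrum
#'
#' Subtracts the mean absorbance over 750-800 nm (where CDOM absorption is
#' negligible) from the whole blank-subtracted spectrum, removing residual
#' instrument offset and scattering baseline. Applying the correction twice
#' is an error (guarded by the `null_corrected` flag).
#'
#' @param spec an [absorbance_spectrum()] with `blank_subtracted = TRUE`
#'   covering 750-800 nm.
#' @param null_window wavelength window (nm) whose mean is subtracted.
#' @return the corrected `absorbance_spectrum` (`null_corrected = TRUE`).
#' @export
null_point_correct <- function(spec, null_window = c(750, 800)) {
  stop_if_not(inherits(spec, "absorbance_spectrum"),
              "spec must be an absorbance_spectrum")
  stop_if_not(spec$blank_subtracted,
              "blank must be subtracted before null-point correction")
  if (spec$null_corrected)
    stop("spectrum is already null-corrected", call. = FALSE)
  sel <- spec$wavelength >= null_window[1] & spec$wavelength <= null_window[2]
  stop_if_not(sum(sel) >= 2,
              "spectrum does not cover the null window (750-800 nm)")
  spec$A <- spec$A - mean(spec$A[sel])
  spec$null_corrected <- TRUE
  spec
}

#' Convert decadic absorbance to Napierian absorption coefficients
#'
#' a(lambda) = 2.303 * A(lambda) / L with L the cuvette pathlength in m.
#' The conventional factor 2.303 is used as printed in the index literature
#' (not ln 10 to full precision). Requires a null-corrected spectrum.
#'
#' @param spec a null-corrected [absorbance_spectrum()].
#' @return data.frame with `wavelength` (nm) and `a` (1/m).
#' @export
#' @examples
#' s <- absorbance_spectrum(200:800, rep(0.05, 601), pathlength = 0.10,
#'                          null_corrected = TRUE)
#' head(absorbance_to_absorption(s))  # a = 1.1515 1/m
absorbance_to_absorption <- function(spec) {
  stop_if_not(inherits(spec, "absorbance_spectrum"),
              "spec must be an absorbance_spectrum")
  stop_if_not(spec$null_corrected,
              "apply null_point_correct() before converting to absorption")
  data.frame(wavelength = spec$wavelength,
             a = 2.303 * spec$A / spec$pathlength)
}

#' Spectral slope of CDOM absorption over a wavelength window
#'
#' Fits ln a(lambda) = ln a(lambda_ref) - S * (lambda - lambda_ref) by
#' linear least squares over the window and returns S (1/nm), positive for
#' spectra that decrease with wavelength (the universal CDOM convention).
#' Non-positive absorption values inside the window are masked before the
#' fit.
#'
#' @param wavelength nm.
#' @param a Napierian absorption coefficients (1/m).
#' @param window `c(lo, hi)` in nm.
#' @return S in 1/nm.
#' @export
fit_slope <- function(wavelength, a, window) {
  stop_if_not(length(wavelength) == length(a), "lengths differ")
  sel <- wavelength >= window[1] & wavelength <= window[2] &
    is.finite(a) & a > 0
  if (sum(sel) < 5)
    stop("fewer than 5 valid points in the slope window", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, wavelength[sel]), log(a[sel]))
  -unname(fit$coefficients[2])
}

#' CDOM optical indices from an absorbance spectrum
#'
#' Computes the standard CDOM characterization set:
#' * `a320`: Napierian absorption at 320 nm (1/m), overall CDOM amount;
#' * `SUVA254`: decadic absorbance per metre at 254 nm / DOC
#'   (L mg-1 m-1), aromaticity proxy;
#' * `S289`: spectral slope over 279-299 nm (1/nm);
#' * `S285`: slope over 275-295 nm; `S375`: slope over 350-400 nm;
#' * `S_R = S285 / S375`: slope ratio, inversely related to molecular
#'   weight (exactly 1 for a single-exponential spectrum);
#' * `a_star_cdom = a320 / DOC` (m2 g-1), DOC-specific absorption.
#'
#' @param spec a null-corrected [absorbance_spectrum()].
#' @param DOC dissolved organic carbon, mg/L (> 0).
#' @param s289_window window for the short-UV slope; default `c(279, 299)`.
#' @return one-row data.frame with the indices above.
#' @export
cdom_indices <- function(spec, DOC, s289_window = c(279, 299)) {
  stop_if_not(is.numeric(DOC) && length(DOC) == 1 && DOC > 0,
              "DOC must be a single value > 0")
  ab <- absorbance_to_absorption(spec)
  interp_a <- function(w) stats::approx(ab$wavelength, ab$a, xout = w)$y
  interp_A <- function(w) stats::approx(spec$wavelength, spec$A, xout = w)$y
  a320 <- interp_a(320)
  A254_per_m <- interp_A(254) / spec$pathlength   # decadic, per metre
  S289 <- fit_slope(ab$wavelength, ab$a, s289_window)
  S285 <- fit_slope(ab$wavelength, ab$a, c(275, 295))
  S375 <- fit_slope(ab$wavelength, ab$a, c(350, 400))
  data.frame(a320 = a320,
             SUVA254 = A254_per_m / DOC,
             S289 = S289, S285 = S285, S375 = S375,
             S_R = S285 / S375,
             a_star_cdom = a320 / DOC)
}

#' Pure-water absorption coefficients on a wavelength grid
#'
#' Loads the bundled pure-water Napierian absorption table (a synthetic
#' smooth compilation approximating published pure-water values; see the
#' header of `inst/extdata/water_absorption_synthetic.csv`) and
#' interpolates it to the requested grid with a natural cubic spline.
#'
#' @param wavelength nm, within 300-720.
#' @return a_w in 1/m at each requested wavelength.
#' @export
water_absorption <- function(wavelength) {
  path <- system.file("extdata", "water_absorption_synthetic.csv",
                      package = "underice", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  stop_if_not(all(wavelength >= min(tab$wavelength_nm) &
                    wavelength <= max(tab$wavelength_nm)),
              "requested wavelengths outside the bundled 300-720 nm table")
  stats::spline(tab$wavelength_nm, tab$a_w_m1, xout = wavelength,
                method = "natural")$y
}

#' Partition total absorption among water, CDOM, phytoplankton and NAP
#'
#' Splits measured particulate absorption into non-algal particles (NAP)
#' and phytoplankton by fitting the exponential NAP model
#' a_NAP(lambda) = a_NAP(443) * exp(-S_NAP * (lambda - 443)) over
#' NAP-dominated windows where pigment absorption is minimal (defaults
#' 380-420 and 600-650 nm), then a_ph = a_particulate - a_NAP clipped at 0.
#' The total a_t is assembled as a_w + a_CDOM + a_ph + a_NAP, so the four
#' components sum to a_t exactly by construction.
#'
#' @param wavelength common grid, nm.
#' @param a_cdom CDOM absorption, 1/m.
#' @param a_particulate total particulate absorption, 1/m.
#' @param a_w pure-water absorption, 1/m; defaults to
#'   [water_absorption()] on the grid.
#' @param nap_windows list of `c(lo, hi)` windows for the NAP fit.
#' @return data.frame of class `absorption_partition` with `wavelength`,
#'   `a_w`, `a_cdom`, `a_ph`, `a_nap`, `a_t`; attributes `S_NAP`,
#'   `n_clipped` (points where a_ph was clipped to 0) and `flagged`
#'   (TRUE when > 20% of particulate points were negative).
#' @export
partition_budget <- function(wavelength, a_cdom, a_particulate, a_w = NULL,
                             nap_windows = list(c(380, 420), c(600, 650))) {
  check_strictly_increasing(wavelength, "wavelength")
  stop_if_not(length(a_cdom) == length(wavelength) &&
                length(a_particulate) == length(wavelength),
              "spectra must share the wavelength grid")
  if (is.null(a_w)) a_w <- water_absorption(wavelength)
  stop_if_not(length(a_w) == length(wavelength), "a_w length mismatch")
  flagged <- mean(a_particulate < 0) > 0.20
  in_win <- Reduce(`|`, lapply(nap_windows, function(w)
    wavelength >= w[1] & wavelength <= w[2]))
  sel <- in_win & is.finite(a_particulate) & a_particulate > 0
  stop_if_not(sum(sel) >= 5, "too few positive points in NAP windows")
  fit <- stats::lm.fit(cbind(1, wavelength[sel] - 443),
                       log(a_particulate[sel]))
  S_nap <- -unname(fit$coefficients[2])
  a_nap <- exp(unname(fit$coefficients[1])) *
    exp(-S_nap * (wavelength - 443))
  a_ph <- a_particulate - a_nap
  n_clipped <- sum(a_ph < 0)
  a_ph <- pmax(a_ph, 0)
  out <- data.frame(wavelength = wavelength, a_w = a_w, a_cdom = a_cdom,
                    a_ph = a_ph, a_nap = a_nap,
                    a_t = a_w + a_cdom + a_ph + a_nap)
  attr(out, "S_NAP") <- S_nap
  attr(out, "n_clipped") <- n_clipped
  attr(out, "flagged") <- flagged
  class(out) <- c("absorption_partition", class(out))
  out
}

#' In-situ light absorption shares per optical component
#'
#' Weights each absorption component by the downwelling spectral irradiance
#' at the sampling depth and integrates over 400-700 nm:
#' share_x = 100 * sum(a_x * E_d) / sum(a_t * E_d). The four shares sum to
#' 100 by construction.
#'
#' @param partition output of [partition_budget()].
#' @param Ed downwelling irradiance at the sampling depth on the partition's
#'   wavelength grid (any units; only relative shape matters).
#' @param band integration band, default `c(400, 700)` nm.
#' @return named vector of percentages for `water`, `cdom`,
#'   `phytoplankton`, `nap`.
#' @export
in_situ_contributions <- function(partition, Ed, band = c(400, 700)) {
  stop_if_not(inherits(partition, "absorption_partition"),
              "partition must come from partition_budget()")
  stop_if_not(length(Ed) == nrow(partition), "Ed grid mismatch")
  sel <- partition$wavelength >= band[1] & partition$wavelength <= band[2]
  stop_if_not(any(sel), "band outside partition grid")
  w <- Ed[sel]
  stop_if_not(any(w > 0), "irradiance is zero over the whole band")
  tot <- sum(partition$a_t[sel] * w)
  shares <- c(
    water         = sum(partition$a_w[sel]   * w),
    cdom          = sum(partition$a_cdom[sel] * w),
    phytoplankton = sum(partition$a_ph[sel]  * w),
    nap           = sum(partition$a_nap[sel] * w)
  ) / tot * 100
  shares
}
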