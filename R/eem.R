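# Excitation-emission matrices (EEMs) and their correction chain.
#
# Corrections must be applied in the fixed order
#   blank subtraction -> inner-filter -> scatter excision -> Raman
# normalization; each step records itself in `corrections` and refuses to
# run out of order. Scatter cells are masked (NA), never interpolated.

.eem_steps <- c("blank", "inner_filter", "scatter", "raman")

#' Construct an excitation-emission matrix
#'
#' @param ex excitation wavelengths, nm, strictly increasing (typically
#'   250-450 at 10 nm).
#' @param em emission wavelengths, nm, strictly increasing (typically
#'   300-560 at 2 nm).
#' @param intensity matrix `length(em)` x `length(ex)` of fluorescence
#'   intensity (arbitrary units before Raman normalization); NA marks
#'   excised cells.
#' @param corrections character vector of correction steps already applied,
#'   in order; subset of `c("blank", "inner_filter", "scatter", "raman")`.
#' @return object of class `eem`.
#' @export
eem <- function(ex, em, intensity, corrections = character()) {
  check_strictly_increasing(ex, "excitation grid")
  check_strictly_increasing(em, "emission grid")
  intensity <- as.matrix(intensity)
  stop_if_not(nrow(intensity) == length(em) && ncol(intensity) == length(ex),
              "intensity must be emission x excitation")
  stop_if_not(all(corrections %in% .eem_steps),
              "unknown correction step")
  stop_if_not(identical(corrections,
                        .eem_steps[.eem_steps %in% corrections]),
              "corrections out of order")
  structure(list(ex = ex, em = em, intensity = intensity,
                 corrections = corrections),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat("eem:", length(x$ex), "ex x", length(x$em), "em (",
      min(x$ex), "-", max(x$ex), "/", min(x$em), "-", max(x$em), "nm );",
      sum(is.na(x$intensity)), "masked cells; corrections:",
      if (length(x$corrections)) paste(x$corrections, collapse = " -> ")
      else "none", "\n")
  invisible(x)
}

# guard: step may only be applied when all earlier steps are done and no
# later step has run
.check_step <- function(x, step) {
  stop_if_not(inherits(x, "eem"), "not an eem")
  i <- match(step, .eem_steps)
  if (step %in% x$corrections)
    stop(sprintf("'%s' correction already applied", step), call. = FALSE)
  earlier <- .eem_steps[seq_len(i - 1)]
  missing <- setdiff(earlier, x$corrections)
  if (length(missing))
    stop(sprintf("'%s' requires prior steps: %s", step,
                 paste(missing, collapse = ", ")), call. = FALSE)
  later <- .eem_steps[-seq_len(i)]
  if (any(later %in% x$corrections))
    stop(sprintf("'%s' must precede %s", step,
                 paste(intersect(later, x$corrections), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Subtract a water blank EEM
#'
#' @param x sample [eem()].
#' @param blank blank [eem()] on the same grids.
#' @return blank-subtracted `eem`.
#' @export
blank_subtract <- function(x, blank) {
  .check_step(x, "blank")
  stop_if_not(inherits(blank, "eem") && identical(blank$ex, x$ex) &&
                identical(blank$em, x$em), "blank grid mismatch")
  x$intensity <- x$intensity - blank$intensity
  x$corrections <- c(x$corrections, "blank")
  x
}

#' Inner-filter effect correction from the companion absorbance spectrum
#'
#' Multiplies each cell by 10^((A_ex + A_em)/2), the standard absorbance-
#' based inner-filter correction, with A the decadic absorbance rescaled to
#' a 1 cm pathlength. Warns (and flags) when A exceeds 1.5 anywhere in
#' range, where the correction becomes unreliable.
#'
#' @param x a blank-subtracted [eem()].
#' @param absorbance an [absorbance_spectrum()] covering 250-560 nm.
#' @return corrected `eem` (attribute `ife_unreliable` set if A > 1.5).
#' @export
inner_filter_correct <- function(x, absorbance) {
  .check_step(x, "inner_filter")
  stop_if_not(inherits(absorbance, "absorbance_spectrum"),
              "absorbance must be an absorbance_spectrum")
  rng <- range(c(x$ex, x$em))
  stop_if_not(min(absorbance$wavelength) <= rng[1] &&
                max(absorbance$wavelength) >= rng[2],
              "absorbance must cover the EEM wavelength range")
  # rescale to 1 cm equivalent pathlength
  A1cm <- absorbance$A * (0.01 / absorbance$pathlength)
  interp <- function(w) stats::approx(absorbance$wavelength, A1cm,
                                      xout = w)$y
  A_ex <- interp(x$ex); A_em <- interp(x$em)
  if (any(c(A_ex, A_em) > 1.5)) {
    warning("absorbance > 1.5 in range: inner-filter correction unreliable")
    attr(x, "ife_unreliable") <- TRUE
  }
  factor <- 10^(outer(A_em, A_ex, `+`) / 2)
  x$intensity <- x$intensity * factor
  x$corrections <- c(x$corrections, "inner_filter")
  x
}

# emission wavelength of the water Raman line (3382 cm-1 shift) for a given
# excitation wavelength, both nm
raman_emission <- function(ex) 1 / (1 / ex - 3382e-7)

#' Excise Rayleigh and Raman scatter ridges
#'
#' Masks (sets to NA) cells within `w1` nm of the first-order Rayleigh line
#' (em = ex), within `w2` nm of the second-order line (em = 2 ex) and
#' within `w_raman` nm of the water Raman line (3382 cm-1 shift from the
#' excitation). Masking is idempotent; masked cells are treated as missing
#' by the PARAFAC fit, never interpolated.
#'
#' @param x an [eem()] with blank and inner-filter corrections applied.
#' @param w1,w2,w_raman half-widths in nm (defaults 15, 15, 5).
#' @return `eem` with scatter cells masked.
#' @export
excise_scatter <- function(x, w1 = 15, w2 = 15, w_raman = 5) {
  # masking is idempotent: re-excising an already-excised EEM is a no-op,
  # unlike the arithmetic corrections which must not be applied twice
  already <- "scatter" %in% x$corrections
  if (!already) .check_step(x, "scatter")
  em_g <- matrix(x$em, nrow = length(x$em), ncol = length(x$ex))
  ex_g <- matrix(x$ex, nrow = length(x$em), ncol = length(x$ex),
                 byrow = TRUE)
  ram <- raman_emission(ex_g)
  bad <- abs(em_g - ex_g) <= w1 | abs(em_g - 2 * ex_g) <= w2 |
    abs(em_g - ram) <= w_raman
  x$intensity[bad] <- NA_real_
  if (!already) x$corrections <- c(x$corrections, "scatter")
  x
}

#' Area of the water Raman peak of a blank at excitation 350 nm
#'
#' Trapezoidal integral of the blank's emission scan at ex = 350 nm over
#' em 371-428 nm, the normalization constant for Raman units.
#'
#' @param blank a blank [eem()] whose excitation grid contains 350 nm.
#' @param em_window integration window, nm.
#' @return Raman peak area (intensity units * nm).
#' @export
raman_area <- function(blank, em_window = c(371, 428)) {
  stop_if_not(inherits(blank, "eem"), "blank must be an eem")
  j <- which(abs(blank$ex - 350) < 1e-9)
  stop_if_not(length(j) == 1, "blank must include excitation 350 nm")
  sel <- blank$em >= em_window[1] & blank$em <= em_window[2]
  stop_if_not(sum(sel) >= 2, "blank does not cover the Raman window")
  y <- blank$intensity[sel, j]
  stop_if_not(all(is.finite(y)), "masked cells inside the Raman window")
  trapz_(blank$em[sel], y)
}

#' Standardize an EEM to Raman units
#'
#' Divides all intensities by the Raman peak area of the water blank
#' ([raman_area()]). The result is independent of the instrument's
#' arbitrary gain, provided sample and blank share it.
#'
#' @param x an [eem()] with earlier corrections applied.
#' @param blank the water blank `eem` (uncorrected intensities).
#' @return `eem` in Raman units.
#' @export
raman_normalize <- function(x, blank) {
  .check_step(x, "raman")
  area <- raman_area(blank)
  stop_if_not(is.finite(area) && area > 0, "Raman peak area must be > 0")
  x$intensity <- x$intensity / area
  x$corrections <- c(x$corrections, "raman")
  x
}

#' Fluorescence index (FI)
#'
#' Ratio of emission intensities at 450 nm and 500 nm under excitation at
#' 370 nm; an indicator of microbial versus terrestrial DOM origin. If
#' 370 nm is absent from the excitation grid the two neighbouring columns
#' are linearly interpolated. Being a ratio, FI is invariant under Raman
#' normalization.
#'
#' @param x an [eem()].
#' @return FI (dimensionless); NA with a warning if the denominator is
#'   non-positive or cells are masked.
#' @export
fluorescence_index <- function(x) {
  stop_if_not(inherits(x, "eem"), "x must be an eem")
  col_at <- function(w) {
    j <- which(abs(x$ex - w) < 1e-9)
    if (length(j) == 1) return(x$intensity[, j])
    below <- max(which(x$ex < w)); above <- min(which(x$ex > w))
    stop_if_not(is.finite(below) && is.finite(above),
                "excitation grid does not bracket 370 nm")
    f <- (w - x$ex[below]) / (x$ex[above] - x$ex[below])
    (1 - f) * x$intensity[, below] + f * x$intensity[, above]
  }
  scan <- col_at(370)
  val_at <- function(w) {
    i <- which(abs(x$em - w) < 1e-9)
    stop_if_not(length(i) == 1, sprintf("emission grid lacks %g nm", w))
    scan[i]
  }
  num <- val_at(450); den <- val_at(500)
  if (!is.finite(den) || den <= 0 || !is.finite(num)) {
    warning("fluorescence index undefined (masked or non-positive cells)")
    return(NA_real_)
  }
  num / den
}
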