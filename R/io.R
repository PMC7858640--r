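# CSV dialects used by the pipeline: comma-separated, UTF-8, '.' decimal,
# header required. One writer/reader pair per input kind.

#' Write / read depth profiles as long-format CSV
#'
#' Columns: `depth_m`, `variable`, `value`, `unit`, `flag`.
#'
#' @param profiles data.frame with one column per variable plus `depth`.
#' @param path file path.
#' @param units named character vector mapping variable name to unit.
#' @return (reader) data.frame in wide format with attribute `units`.
#' @export
write_profile_csv <- function(profiles, path, units = character()) {
  vars <- setdiff(names(profiles), "depth")
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(depth_m = profiles$depth, variable = v,
               value = profiles[[v]],
               unit = if (v %in% names(units)) units[[v]] else "",
               flag = "ok")))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  long <- utils::read.csv(path)
  stop_if_not(all(c("depth_m", "variable", "value") %in% names(long)),
              sprintf("%s: not a profile CSV (depth_m/variable/value)", path))
  wide <- stats::reshape(long[c("depth_m", "variable", "value")],
                         idvar = "depth_m", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  names(wide)[1] <- "depth"
  wide <- wide[order(wide$depth), , drop = FALSE]
  rownames(wide) <- NULL
  units <- unique(long[c("variable", "unit")])
  attr(wide, "units") <- stats::setNames(units$unit, units$variable)
  wide
}

#' Write / read a spectral irradiance profile CSV
#'
#' Rows are wavelengths; columns are depth records labelled `air`, `JBI`
#' or numeric metres. Downwelling and upwelling matrices go to separate
#' files.
#'
#' @param profile an [irradiance_profile()].
#' @param path_ed,path_eu file paths (`path_eu` optional).
#' @return (reader) an `irradiance_profile`.
#' @export
write_irradiance_csv <- function(profile, path_ed, path_eu = NULL) {
  df <- data.frame(wavelength_nm = profile$wavelength)
  mat <- as.data.frame(profile$Ed)
  names(mat) <- profile$labels
  utils::write.csv(cbind(df, mat), path_ed, row.names = FALSE, quote = FALSE)
  if (!is.null(path_eu) && !is.null(profile$Eu)) {
    mat_u <- as.data.frame(profile$Eu)
    names(mat_u) <- profile$labels
    utils::write.csv(cbind(df, mat_u), path_eu, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path_ed)
}

#' @rdname write_irradiance_csv
#' @param jbi_depth depth (m) assigned to the `JBI` column on read.
#' @export
read_irradiance_csv <- function(path_ed, path_eu = NULL, jbi_depth = 2.0) {
  tab <- utils::read.csv(path_ed, check.names = FALSE)
  stop_if_not(names(tab)[1] == "wavelength_nm",
              sprintf("%s: first column must be wavelength_nm", path_ed))
  labels <- names(tab)[-1]
  depth <- suppressWarnings(as.numeric(labels))
  depth[labels == "JBI"] <- jbi_depth
  Ed <- as.matrix(tab[, -1])
  Eu <- NULL
  if (!is.null(path_eu) && file.exists(path_eu)) {
    tab_u <- utils::read.csv(path_eu, check.names = FALSE)
    Eu <- as.matrix(tab_u[, -1])
  }
  irradiance_profile(tab$wavelength_nm, depth, Ed, Eu, labels = labels)
}

#' Write / read an absorbance spectrum CSV with a metadata header block
#'
#' Metadata lines (`# key: value`) precede the `wavelength_nm,A` table;
#' pathlength and correction flags round-trip through them.
#'
#' @param spec an [absorbance_spectrum()].
#' @param path file path.
#' @return (reader) an `absorbance_spectrum`.
#' @export
write_absorbance_csv <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pathlength_m: %g", spec$pathlength),
               sprintf("# blank_subtracted: %s", spec$blank_subtracted),
               sprintf("# null_corrected: %s", spec$null_corrected)), con)
  utils::write.csv(data.frame(wavelength_nm = spec$wavelength, A = spec$A),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_absorbance_csv
#' @export
read_absorbance_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", m), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                             invert = TRUE)))
  absorbance_spectrum(tab$wavelength_nm, tab$A,
                      pathlength = as.numeric(meta$pathlength_m %||% 0.10),
                      blank_subtracted =
                        as.logical(meta$blank_subtracted %||% TRUE),
                      null_corrected =
                        as.logical(meta$null_corrected %||% FALSE))
}

#' Write / read an EEM matrix CSV
#'
#' First column is emission (nm); the header row carries the excitation
#' grid (`ex_250`, `ex_260`, ...). Masked cells are empty fields.
#'
#' @param x an [eem()].
#' @param path file path.
#' @param corrections correction state to assume on read (the manifest
#'   normally supplies it).
#' @return (reader) an `eem`.
#' @export
write_eem_csv <- function(x, path) {
  df <- data.frame(emission_nm = x$em)
  mat <- as.data.frame(x$intensity)
  names(mat) <- paste0("ex_", x$ex)
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_eem_csv
#' @export
read_eem_csv <- function(path, corrections = character()) {
  tab <- utils::read.csv(path, check.names = FALSE)
  stop_if_not(names(tab)[1] == "emission_nm",
              sprintf("%s: first column must be emission_nm", path))
  ex <- as.numeric(sub("^ex_", "", names(tab)[-1]))
  eem(ex, tab$emission_nm, as.matrix(tab[, -1]), corrections = corrections)
}
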