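# End-to-end pipeline over a directory of inputs (real or synthetic).

#' Build and validate a pipeline configuration
#'
#' @param input_dir directory of input files (layout as written by
#'   [generate_synthetic_campaign()]).
#' @param output_dir directory for per-stage outputs (created).
#' @param seed master seed for stochastic stages (PARAFAC restarts).
#' @param threshold_N2 stability threshold for layer detection, 1/s2.
#' @param parafac_K PARAFAC component count.
#' @param parafac_restarts random restarts for the PARAFAC fit.
#' @param gas_bounds integration bounds `c(z_top, z_bottom)` for areal gas
#'   storage, m.
#' @param pigment_bounds integration bounds for the pigment stock, m.
#' @param s289_window window for the S289 slope, nm.
#' @param jbi_depth depth assigned to the "JBI" irradiance record, m.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            seed = 1L,
                            threshold_N2 = 5e-5,
                            parafac_K = 3,
                            parafac_restarts = 10,
                            gas_bounds = c(2, 9),
                            pigment_bounds = c(1.5, 9.0),
                            s289_window = c(279, 299),
                            jbi_depth = 2.0) {
  stop_if_not(dir.exists(input_dir), "input_dir does not exist")
  stop_if_not(is.numeric(threshold_N2) && threshold_N2 > 0,
              "threshold_N2 must be > 0")
  stop_if_not(parafac_K >= 1 && parafac_restarts >= 1,
              "parafac_K and parafac_restarts must be >= 1")
  stop_if_not(gas_bounds[2] > gas_bounds[1] &&
                pigment_bounds[2] > pigment_bounds[1],
              "integration bounds must be increasing")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 seed = as.integer(seed), threshold_N2 = threshold_N2,
                 parafac_K = parafac_K,
                 parafac_restarts = parafac_restarts,
                 gas_bounds = gas_bounds, pigment_bounds = pigment_bounds,
                 s289_window = s289_window, jbi_depth = jbi_depth),
            class = "pipeline_config")
}

#' Write a full synthetic campaign to a directory
#'
#' Generates every pipeline input from a [lake_scenario()] and writes the
#' CSV files the pipeline reads, plus a `ground_truth.json` sidecar with
#' the generating parameters and true values for test harnesses.
#'
#' @param scenario a [lake_scenario()].
#' @param dir output directory (created).
#' @param benthic_chl benthic-mat chlorophyll stocks per site, mg m-2,
#'   written alongside the water-column pigment samples.
#' @return `dir`, invisibly.
#' @export
generate_synthetic_campaign <- function(scenario, dir,
                                        benthic_chl = c(84, 165, 148)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  ctd <- generate_ctd(scenario)
  write_profile_csv(ctd, p("ctd.csv"),
                    units = c(temperature = "degC",
                              conductance = "uS/cm",
                              oxygen_sat = "%sat", chl_a = "ug/L"))

  prof <- generate_irradiance(scenario)
  write_irradiance_csv(prof, p("irradiance_ed.csv"), p("irradiance_eu.csv"))

  specs <- generate_cdom_spectra(scenario)
  for (i in seq_along(specs))
    write_absorbance_csv(specs[[i]], p(sprintf("cdom_%02d.csv", i)))

  eg <- generate_eems(scenario)
  for (i in seq_along(eg$eems))
    write_eem_csv(eg$eems[[i]], p(sprintf("eem_%02d.csv", i)))
  write_eem_csv(eg$blank, p("eem_blank.csv"))
  manifest <- data.frame(
    sample = seq_along(eg$eems),
    eem_file = sprintf("eem_%02d.csv", seq_along(eg$eems)),
    blank_file = "eem_blank.csv",
    corrections = vapply(eg$eems, function(e)
      paste(e$corrections, collapse = ";"), ""))
  utils::write.csv(manifest, p("eem_manifest.csv"), row.names = FALSE,
                   quote = FALSE)

  for (date in c("june", "july")) {
    hs <- generate_headspace(scenario, date)
    utils::write.csv(hs, p(sprintf("headspace_%s.csv", date)),
                     row.names = FALSE, quote = FALSE)
  }

  # discrete pigment samples at two depths (triplicates) + benthic stocks
  tctd <- true_ctd(scenario)
  pig_depths <- rep(c(2.2, 7.5), each = 3)
  chl <- stats::approx(tctd$depth, tctd$chl_a, xout = pig_depths,
                       rule = 2)$y
  pig <- rbind(
    data.frame(site = "WH1", compartment = "water_column",
               pigment = "chl_a", depth_m = pig_depths, value = chl,
               unit = "ug/L"),
    data.frame(site = paste0("WH", seq_along(benthic_chl)),
               compartment = "benthic", pigment = "chl_a",
               depth_m = NA, value = benthic_chl, unit = "mg/m2"))
  utils::write.csv(pig, p("pigments.csv"), row.names = FALSE, quote = FALSE)

  truth <- list(
    scenario = scenario[setdiff(names(scenario), character())],
    kd_true = true_kd(scenario),
    gas_true_june = true_gas_profiles(scenario, "june"),
    gas_true_july = true_gas_profiles(scenario, "july"),
    eem_truth = eg$truth
  )
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}

.stage <- function(report, name, fun) {
  res <- tryCatch(list(ok = TRUE, value = fun(), error = NULL),
                  error = function(e)
                    list(ok = FALSE, value = NULL,
                         error = conditionMessage(e)))
  report$stages[[name]] <- res
  report
}

#' Run the full under-ice analysis pipeline on a directory of inputs
#'
#' Executes hydrophysics, optics, CDOM, fluorescence (PARAFAC), gases and
#' pigment-stock stages over the files in `config$input_dir`, writing
#' per-stage CSV outputs and a JSON run manifest to `config$output_dir`.
#' A failing stage (e.g. a missing input) is isolated: its error is
#' recorded in the report and the remaining stages still run.
#'
#' @param config a [pipeline_config()].
#' @return report list: per-stage `ok`/`value`/`error`, plus the manifest.
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ip <- function(...) file.path(config$input_dir, ...)
  op <- function(...) file.path(config$output_dir, ...)
  report <- list(stages = list())

  report <- .stage(report, "hydrophysics", function() {
    ctd <- read_profile_csv(ip("ctd.csv"))
    dens <- density_profile(ctd$depth, ctd$temperature, ctd$conductance)
    stab <- brunt_vaisala(dens$depth, dens$rho_TC)
    layers <- detect_layers(stab, config$threshold_N2)
    utils::write.csv(dens, op("density.csv"), row.names = FALSE)
    utils::write.csv(stab, op("stability.csv"), row.names = FALSE)
    list(layers = layers, n_depths = nrow(ctd))
  })

  report <- .stage(report, "optics", function() {
    prof <- read_irradiance_csv(ip("irradiance_ed.csv"),
                                ip("irradiance_eu.csv"),
                                jbi_depth = config$jbi_depth)
    kd <- kd_profile(prof)
    kd_par <- kd_band(prof, "PAR")
    utils::write.csv(kd, op("kd_spectral.csv"), row.names = FALSE)
    utils::write.csv(kd_par, op("kd_par.csv"), row.names = FALSE)
    deepest <- max(prof$depth, na.rm = TRUE)
    bands <- vapply(c("TOTAL", "PAR", "UVR"), function(b)
      band_energy(prof, deepest, b) / band_energy(prof, NA, b) * 100,
      0)
    list(kd_par = kd_par, pct_at_bottom = bands)
  })

  report <- .stage(report, "cdom", function() {
    files <- sort(list.files(config$input_dir, "^cdom_.*\\.csv$",
                             full.names = TRUE))
    stop_if_not(length(files) > 0, "no CDOM absorbance files")
    idx <- do.call(rbind, lapply(files, function(f) {
      sp <- null_point_correct(read_absorbance_csv(f))
      cdom_indices(sp, DOC = 2.0, s289_window = config$s289_window)
    }))
    idx$file <- basename(files)
    utils::write.csv(idx, op("cdom_indices.csv"), row.names = FALSE)
    idx
  })

  report <- .stage(report, "fluorescence", function() {
    man <- utils::read.csv(ip("eem_manifest.csv"))
    stop_if_not(file.exists(ip(man$eem_file[1])), "EEM files missing")
    blank <- read_eem_csv(ip(man$blank_file[1]))
    eems <- lapply(seq_len(nrow(man)), function(i) {
      corr <- strsplit(man$corrections[i], ";")[[1]]
      x <- read_eem_csv(ip(man$eem_file[i]), corrections = corr)
      if (!("scatter" %in% x$corrections)) x <- excise_scatter(x)
      if (!("raman" %in% x$corrections)) x <- raman_normalize(x, blank)
      x
    })
    model <- parafac_fit(eems, K = config$parafac_K,
                         restarts = config$parafac_restarts,
                         seed = config$seed)
    pct <- component_contributions(model)
    fi <- vapply(eems, fluorescence_index, 0)
    utils::write.csv(cbind(as.data.frame(pct), FI = fi),
                     op("parafac_contributions.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(model$em_loadings),
                     op("parafac_em_loadings.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(model$ex_loadings),
                     op("parafac_ex_loadings.csv"), row.names = FALSE)
    list(model = model, pct = pct, FI = fi)
  })

  report <- .stage(report, "gases", function() {
    read_hs <- function(date) {
      tab <- utils::read.csv(ip(sprintf("headspace_%s.csv", date)))
      class(tab) <- c("headspace_sample", class(tab))
      invert_headspace(tab)
    }
    add_sat <- function(d) {
      d$saturation <- NA_real_
      for (g in unique(d$gas)) {
        i <- d$gas == g
        d$saturation[i] <- gas_saturation(d$concentration[i], g,
                                          d$in_situ_T[i], d$ambient_ppm[i])
      }
      d
    }
    june <- add_sat(read_hs("june")); july <- add_sat(read_hs("july"))
    storage <- do.call(rbind, lapply(unique(june$gas), function(g) {
      j1 <- june[june$gas == g, ]; j2 <- july[july$gas == g, ]
      data.frame(
        gas = g,
        storage_june = as.numeric(column_storage(
          j1$depth, j1$concentration, config$gas_bounds[1],
          config$gas_bounds[2])),
        storage_july = as.numeric(column_storage(
          j2$depth, j2$concentration, config$gas_bounds[1],
          config$gas_bounds[2])),
        change_pct = storage_change(j1$depth, j1$concentration,
                                    j2$depth, j2$concentration,
                                    config$gas_bounds[1],
                                    config$gas_bounds[2]))
    }))
    utils::write.csv(june, op("gas_june.csv"), row.names = FALSE)
    utils::write.csv(july, op("gas_july.csv"), row.names = FALSE)
    utils::write.csv(storage, op("gas_storage.csv"), row.names = FALSE)
    storage
  })

  report <- .stage(report, "stocks", function() {
    pig <- utils::read.csv(ip("pigments.csv"))
    wc <- pig[pig$compartment == "water_column", ]
    stop_if_not(nrow(wc) > 0, "no water-column pigment samples")
    stock <- integrate_water_column(wc$depth_m, wc$value,
                                    config$pigment_bounds[1],
                                    config$pigment_bounds[2])
    ben <- pig[pig$compartment == "benthic", ]
    ratios <- if (nrow(ben) > 0)
      data.frame(site = ben$site,
                 ratio = benthic_pelagic_ratio(ben$value, stock))
    else NULL
    out <- data.frame(water_column_stock_mg_m2 = stock)
    utils::write.csv(out, op("pigment_stock.csv"), row.names = FALSE)
    if (!is.null(ratios))
      utils::write.csv(ratios, op("benthic_pelagic_ratio.csv"),
                       row.names = FALSE)
    list(stock = stock, ratios = ratios)
  })

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("underice")),
    stages_ok = vapply(report$stages, function(s) s$ok, TRUE)
  )
  jsonlite::write_json(manifest, op("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report$manifest <- manifest
  report
}
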