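test_that("generators are pure functions of scenario and seed", {
  sc <- default_scenario(seed = 17)
  expect_identical(generate_ctd(sc), generate_ctd(sc))
  p1 <- generate_irradiance(sc); p2 <- generate_irradiance(sc)
  expect_identical(p1$Ed, p2$Ed)
  e1 <- generate_eems(sc); e2 <- generate_eems(sc)
  expect_identical(e1$truth$scores, e2$truth$scores)
  expect_identical(e1$eems[[3]]$intensity, e2$eems[[3]]$intensity)
  h1 <- generate_headspace(sc); h2 <- generate_headspace(sc)
  expect_identical(h1$measured_ppm, h2$measured_ppm)
  sc2 <- default_scenario(seed = 18)
  expect_false(identical(generate_ctd(sc2)$temperature,
                         generate_ctd(sc)$temperature))
})

test_that("scenario validation enforces the structural invariants", {
  expect_error(lake_scenario(cond_params = c(300, 250, 200)),
               "non-decreasing")
  expect_error(lake_scenario(T_params = c(1, 8, 3)), "6.5")
  expect_error(lake_scenario(layer_bounds = c(8, 4)), "in order")
  expect_error(lake_scenario(kd_scale = c(-1, 1, 1)), "non-negative")
  expect_error(lake_scenario(cdom_S = -0.01), "cdom_S")
  sc <- default_scenario()
  expect_true(all(diff(true_ctd(sc)$conductance) >= 0))
  expect_true(all(true_kd(sc) >= 0))
  eg <- generate_eems(small_eem_scenario(), noise_sd = 0, scatter = FALSE)
  expect_true(all(eg$truth$scores >= 0))
  expect_true(all(eg$truth$em_loadings >= 0))
  expect_true(all(eg$truth$ex_loadings >= 0))
})

test_that("uniform conductivity leaves only the thermal density gradient", {
  sc <- lake_scenario(cond_params = c(200, 200, 200))
  ctd <- generate_ctd(sc, noise_sd = 0)
  dens <- density_profile(ctd$depth, ctd$temperature, ctd$conductance)
  bv_tc <- brunt_vaisala(dens$depth, dens$rho_TC)
  bv_t <- brunt_vaisala(dens$depth, dens$rho_T)
  # a constant salinity still modulates the thermal gradient slightly via
  # the temperature dependence of the haline coefficient (~1% here)
  expect_equal(bv_tc$N2, bv_t$N2, tolerance = 0.02)
  # in the isothermal convective cell N2 is exactly zero
  cell <- bv_tc$depth_mid > sc$layer_bounds[1] + 0.2 &
    bv_tc$depth_mid < sc$layer_bounds[2] - 0.2
  expect_true(all(abs(bv_tc$N2[cell]) < 1e-12))
})

test_that("true CTD profiles carry the imposed biogeochemical structure", {
  sc <- default_scenario()
  tr <- true_ctd(sc)
  cell <- tr$depth > sc$layer_bounds[1] & tr$depth < sc$layer_bounds[2]
  bottom <- tr$depth >= sc$layer_bounds[2]
  expect_true(all(tr$oxygen_sat[cell] > 100))       # supersaturated cell
  expect_equal(max(tr$chl_a), tr$chl_a[nrow(tr)])   # Chl a peak at bottom
  expect_true(all(tr$temperature <= 6.5))
  expect_true(all(diff(tr$conductance) >= 0))
})

test_that("irradiance generator is Beer-Lambert with closed-form checks", {
  # zero attenuation: E_d constant below the ice
  sc0 <- lake_scenario(kd_scale = c(0, 0, 0))
  pr0 <- generate_irradiance(sc0, noise_sd = 0)
  uw <- which(!is.na(pr0$depth))
  for (j in uw[-1])
    expect_equal(pr0$Ed[, j], pr0$Ed[, uw[1]], tolerance = 1e-12)
  # single uniform layer kd = 1: one metre attenuates by e
  sc1 <- lake_scenario(kd_scale = c(1, 1, 1), irradiance_depths = c(2, 3))
  kd_flat <- matrix(1, length(sc1$wavelength_grid), 3)
  pr1 <- generate_irradiance(sc1, noise_sd = 0)
  kdt <- true_kd(sc1)
  expect_equal(pr1$Ed[, 3] / pr1$Ed[, 2], exp(-kdt[, 1]),
               tolerance = 1e-12)
  # imposed flat reflectance is recovered everywhere
  sc <- default_scenario()
  pr <- generate_irradiance(sc, noise_sd = 0)
  for (z in stats::na.omit(pr$depth))
    expect_equal(unique(round(reflectance(pr, z), 12)),
                 sc$reflectance_true)
})

test_that("zero-CDOM scenarios produce flat spectra and exact offsets", {
  sc <- lake_scenario(cdom_a320 = c(0, 0, 0, 0), cdom_offset = 0.02)
  specs <- generate_cdom_spectra(sc, noise_sd = 0)
  for (sp in specs) {
    expect_equal(unique(sp$A), 0.02)     # offset only
    corr <- null_point_correct(sp)
    expect_equal(unique(corr$A), 0)      # exactly removed
  }
})

test_that("rank-1 EEM scenarios give rank-1 matrices", {
  sc <- lake_scenario(eem_n_samples = 4, eem_ex_peaks = 320,
                      eem_ex_sd = 30, eem_em_peaks = 430, eem_em_sd = 35,
                      seed = 5)
  eg <- generate_eems(sc, scatter = FALSE, noise_sd = 0)
  M <- eg$eems[[1]]$intensity
  expect_equal(qr(M)$rank, 1)
  m <- parafac_fit(eg$eems, K = 1, restarts = 2, seed = 3)
  expect_gt(m$fit, 1 - 1e-6)
})

test_that("headspace generator feeds the shared forward model", {
  # include the lake bottom so the deepest record carries the imposed
  # bottom-water saturation
  sc <- lake_scenario(gas_depths = c(seq(2, 9, by = 1), 9.7))
  hs <- generate_headspace(sc, noise_sd = 0)
  inv <- invert_headspace(hs)
  rel <- abs(inv$concentration - inv$true_concentration) /
    inv$true_concentration
  expect_lt(max(rel), 1e-6)
  # saturations at the imposed bottom values
  bot <- inv[inv$depth == max(inv$depth), ]
  for (i in seq_len(nrow(bot))) {
    sat <- gas_saturation(bot$concentration[i], bot$gas[i],
                          bot$in_situ_T[i], bot$ambient_ppm[i])
    expect_equal(sat, sc$gas_bottom_sat[[bot$gas[i]]], tolerance = 1e-4)
  }
})
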