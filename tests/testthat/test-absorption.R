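test_that("null-point correction removes a constant offset exactly", {
  base <- exponential_absorbance()
  shifted <- absorbance_spectrum(base$wavelength, base$A + 0.01,
                                 pathlength = base$pathlength)
  corr <- null_point_correct(shifted)
  # the offset cancels exactly; what remains is the offset-free spectrum
  # minus its own 750-800 nm tail mean
  tail_mean <- mean(base$A[base$wavelength >= 750])
  expect_equal(corr$A, base$A - tail_mean, tolerance = 1e-12)
  expect_true(corr$null_corrected)
  expect_error(null_point_correct(corr), "already")
  # a spectrum that is zero over the tail is unchanged
  wl <- 200:800
  A0 <- ifelse(wl < 700, 0.2, 0)
  z <- null_point_correct(absorbance_spectrum(wl, A0))
  expect_equal(z$A, A0)
})

test_that("absorption coefficients use a = 2.303 A / L", {
  s <- absorbance_spectrum(200:800, rep(0.05, 601), pathlength = 0.10,
                           null_corrected = TRUE)
  a <- absorbance_to_absorption(s)
  expect_equal(unique(a$a), 1.1515)                    # hand evaluation
  z <- absorbance_spectrum(200:800, rep(0, 601), null_corrected = TRUE)
  expect_equal(unique(absorbance_to_absorption(z)$a), 0)
  s2 <- s; s2$A <- 2 * s2$A
  expect_equal(absorbance_to_absorption(s2)$a, 2 * a$a)
  expect_error(absorbance_to_absorption(
    absorbance_spectrum(200:800, rep(0.05, 601))), "null_point")
})

test_that("spectral slope fitting matches a closed-form least-squares oracle", {
  s <- exponential_absorbance(S = 0.018)
  a <- absorbance_to_absorption(s)
  expect_equal(fit_slope(a$wavelength, a$a, c(275, 295)), 0.018,
               tolerance = 1e-10)
  # flat spectrum
  expect_equal(fit_slope(300:400, rep(2, 101), c(320, 360)), 0)
  # random log-linear data vs the closed-form slope
  set.seed(11)
  for (i in 1:10) {
    wl <- 275:295
    S <- runif(1, 0.005, 0.03)
    a0 <- runif(1, 0.1, 5)
    av <- a0 * exp(-S * (wl - 285)) * exp(rnorm(21, 0, 0.02))
    oracle <- -sum((wl - mean(wl)) * (log(av) - mean(log(av)))) /
      sum((wl - mean(wl))^2)
    expect_equal(fit_slope(wl, av, c(275, 295)), oracle, tolerance = 1e-10)
  }
  expect_error(fit_slope(300:400, rep(-1, 101), c(320, 360)), "5 valid")
})

test_that("CDOM indices follow their definitions and conventions", {
  # spectrum scaled so decadic A254 per metre = 2.0
  s <- exponential_absorbance(a320 = 1, S = 0.018)
  A254_per_m <- approx(s$wavelength, s$A, 254)$y / s$pathlength
  scale <- 2.0 / A254_per_m
  s$A <- s$A * scale
  idx <- cdom_indices(s, DOC = 2.0)
  expect_equal(idx$SUVA254, 1.0, tolerance = 1e-9)
  # a* = a320/DOC on the Napierian spectrum
  s2 <- exponential_absorbance(a320 = 0.5)
  idx2 <- cdom_indices(s2, DOC = 1.0)
  expect_equal(idx2$a320, 0.5, tolerance = 1e-9)
  expect_equal(idx2$a_star_cdom, 0.5, tolerance = 1e-9)
  # doubling DOC halves SUVA and a*
  idx3 <- cdom_indices(s2, DOC = 2.0)
  expect_equal(idx3$SUVA254, idx2$SUVA254 / 2)
  expect_equal(idx3$a_star_cdom, idx2$a_star_cdom / 2)
  # single exponential: equal window slopes, S_R = 1 identically
  expect_equal(idx2$S_R, 1, tolerance = 1e-9)
  expect_equal(idx2$S289, 0.018, tolerance = 1e-9)
  expect_error(cdom_indices(s2, DOC = 0), "DOC")
})

test_that("indices are invariant to cuvette pathlength when A scales with L", {
  s10 <- exponential_absorbance(pathlength = 0.10)
  s01 <- exponential_absorbance(pathlength = 0.01)   # A scales with L
  i10 <- cdom_indices(s10, DOC = 2)
  i01 <- cdom_indices(s01, DOC = 2)
  expect_equal(i10, i01, tolerance = 1e-9)
})

test_that("generator roundtrip recovers the CDOM slope through the pipeline", {
  sc <- default_scenario()
  specs <- generate_cdom_spectra(sc, noise_sd = 0)
  for (sp in specs) {
    corr <- null_point_correct(sp)
    a <- absorbance_to_absorption(corr)
    S_hat <- fit_slope(a$wavelength, a$a, c(275, 295))
    expect_equal(S_hat, attr(sp, "true_S"), tolerance = 1e-3)
  }
})

test_that("absorption budget conserves the total and attributes pigment bands", {
  wl <- 300:720
  # purely exponential particulate spectrum: phytoplankton term vanishes
  a_nap_true <- 0.3 * exp(-0.011 * (wl - 443))
  part <- partition_budget(wl, a_cdom = rep(0.1, length(wl)),
                           a_particulate = a_nap_true)
  expect_lt(max(part$a_ph), 1e-6)
  expect_equal(part$a_t, part$a_w + part$a_cdom + part$a_ph + part$a_nap)
  # Gaussian chlorophyll band at 675 nm on top of the NAP exponential
  a_ph_true <- 0.05 * exp(-((wl - 675) / 12)^2 / 2)
  part2 <- partition_budget(wl, rep(0.1, length(wl)),
                            a_nap_true + a_ph_true)
  at675 <- part2$a_ph[wl == 675]
  expect_lt(abs(at675 - 0.05) / 0.05, 0.05)
  expect_equal(part2$a_t,
               part2$a_w + part2$a_cdom + part2$a_ph + part2$a_nap)
  # heavily negative particulate spectra are flagged
  neg <- part2
  expect_true(attr(partition_budget(wl, rep(0.1, length(wl)),
                                    a_nap_true - 0.28), "flagged"))
})

test_that("in-situ absorption shares are irradiance-weighted and sum to 100", {
  wl <- 300:720
  a_nap_true <- 0.3 * exp(-0.011 * (wl - 443))
  a_ph_true <- 0.05 * exp(-((wl - 675) / 12)^2 / 2)
  part <- partition_budget(wl, rep(0.1, length(wl)), a_nap_true + a_ph_true)
  Ed <- exp(-((wl - 550) / 80)^2)
  sh <- in_situ_contributions(part, Ed)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  # flat irradiance: shares equal the unweighted integral ratios
  flat <- in_situ_contributions(part, rep(1, length(wl)))
  sel <- wl >= 400 & wl <= 700
  expect_equal(unname(flat["cdom"]),
               100 * sum(part$a_cdom[sel]) / sum(part$a_t[sel]),
               tolerance = 1e-12)
  # single-component partition: 100% to that component
  only_ph <- part
  only_ph$a_w <- only_ph$a_cdom <- only_ph$a_nap <- rep(0, length(wl))
  only_ph$a_ph <- only_ph$a_t
  expect_equal(unname(in_situ_contributions(only_ph, Ed)["phytoplankton"]),
               100, tolerance = 1e-12)
  expect_error(in_situ_contributions(part, rep(0, length(wl))), "zero")
})

test_that("bundled water absorption table interpolates smoothly", {
  wl <- 300:720
  aw <- water_absorption(wl)
  expect_true(all(aw > 0))
  expect_true(aw[wl == 700] > aw[wl == 500])   # red tail of liquid water
  expect_error(water_absorption(250), "outside")
})
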