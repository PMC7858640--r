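test_that("transmittance is the ratio to incident air irradiance", {
  pr <- flat_irradiance(depths = c(0.001, 1), kd = 1, t_ice = 0.5)
  expect_equal(unique(transmittance(pr, NA)), 1)             # air identity
  expect_equal(unique(transmittance(pr, 1)), 0.5 * exp(-1),
               tolerance = 1e-3)                             # 0.1839
  zero <- flat_irradiance(depths = 1, kd = 0, t_ice = 0)
  expect_equal(unique(transmittance(zero, 1)), 0)
  no_air <- irradiance_profile(400:409, c(1, 2),
                               matrix(1, 10, 2))
  expect_error(transmittance(no_air, 1), "in-air")
})

test_that("reflectance is Eu/Ed with imposed ratios recovered", {
  pr <- flat_irradiance(depths = c(1, 2), reflectance = 0.02)
  expect_equal(unique(reflectance(pr, 1)), 0.02)
  expect_equal(unique(reflectance(pr, 2)), 0.02)
  pr0 <- flat_irradiance(depths = 1, reflectance = 0)
  expect_equal(unique(reflectance(pr0, 1)), 0)
  pr1 <- flat_irradiance(depths = 1, reflectance = 1)
  expect_equal(unique(reflectance(pr1, 1)), 1)
  no_eu <- flat_irradiance(depths = 1)
  expect_error(reflectance(no_eu, 1), "upwelling")
})

test_that("band energies are discrete sums with non-overlapping UVR/PAR", {
  wl <- 278:720
  pr <- irradiance_profile(wl, NA_real_,
                           matrix(1, length(wl), 1), labels = "air")
  expect_equal(band_energy(pr, NA, "TOTAL"), 443)   # count of grid points
  expect_equal(band_energy(pr, NA, "PAR"), 301)     # 400..700 inclusive
  expect_equal(band_energy(pr, NA, "UVR"), 122)     # 278..399, 400 in PAR
  expect_equal(band_energy(pr, NA, "UVR") + band_energy(pr, NA, "PAR") +
                 band_energy(pr, NA, c(701, 720)),
               band_energy(pr, NA, "TOTAL"))
  # linearity
  pr2 <- irradiance_profile(wl, NA_real_, matrix(0.5, length(wl), 1),
                            labels = "air")
  for (b in c("TOTAL", "PAR", "UVR"))
    expect_equal(band_energy(pr2, NA, b), band_energy(pr, NA, b) / 2)
  # spectrum supported only inside PAR: PAR equals TOTAL
  Ed <- matrix(ifelse(wl >= 400 & wl <= 700, 2, 0), ncol = 1)
  pr3 <- irradiance_profile(wl, NA_real_, Ed, labels = "air")
  expect_equal(band_energy(pr3, NA, "PAR"), band_energy(pr3, NA, "TOTAL"))
  expect_error(band_energy(pr, NA, c(100, 200)), "outside")
})

test_that("K_d pairs follow the log-ratio definition with z2 assignment", {
  wl <- 400:409
  Ed <- cbind(rep(100, 10), rep(10, 10))
  pr <- irradiance_profile(wl, c(1, 3), Ed)
  kd <- kd_profile(pr)
  expect_equal(unique(kd$K_d), log(10) / 2, tolerance = 1e-12)  # 1.1513
  expect_equal(unique(kd$z_assigned), 3)
  expect_false(any(kd$apparent))
  same <- irradiance_profile(wl, c(1, 3), cbind(rep(5, 10), rep(5, 10)))
  expect_equal(unique(kd_profile(same)$K_d), 0)
  # air pair flagged apparent
  pr_air <- flat_irradiance(depths = c(0.5, 1.5), kd = 0.7)
  kda <- kd_profile(pr_air)
  expect_true(all(kda$apparent[kda$z_assigned == 0.5]))
  expect_false(any(kda$apparent[kda$z_assigned == 1.5]))
})

test_that("K_d composes as a thickness-weighted mean over stacked strata", {
  wl <- 400:419
  set.seed(7)
  E1 <- runif(20, 50, 100); k1 <- runif(20, 0.1, 1); k2 <- runif(20, 0.1, 1)
  z <- c(1, 2.5, 5)
  E2 <- E1 * exp(-k1 * diff(z)[1]); E3 <- E2 * exp(-k2 * diff(z)[2])
  pr <- irradiance_profile(wl, z, cbind(E1, E2, E3))
  kd <- kd_profile(pr)
  kd12 <- kd$K_d[kd$z_assigned == z[2]]
  kd23 <- kd$K_d[kd$z_assigned == z[3]]
  pr13 <- irradiance_profile(wl, z[c(1, 3)], cbind(E1, E3))
  kd13 <- kd_profile(pr13)$K_d
  w <- diff(z) / (z[3] - z[1])
  expect_equal(kd13, w[1] * kd12 + w[2] * kd23, tolerance = 1e-12)
})

test_that("kd_profile recovers the generator's layered truth without noise", {
  sc <- default_scenario()
  pr <- generate_irradiance(sc, noise_sd = 0)
  kd <- kd_profile(pr)
  kdt <- true_kd(sc)
  layer_of <- function(z1, z2) {
    b <- c(sc$ice_thickness, sc$layer_bounds, sc$max_depth)
    l1 <- findInterval(z1 + 1e-9, b); l2 <- findInterval(z2 - 1e-9, b)
    if (l1 == l2) l1 else NA
  }
  pairs <- unique(kd[, c("z_assigned", "pair", "apparent")])
  zs <- sort(unique(c(0, na.omit(pr$depth))))
  checked <- 0
  for (i in seq_len(nrow(pairs))) {
    if (pairs$apparent[i]) next
    z2 <- pairs$z_assigned[i]
    z1 <- zs[which(abs(zs - z2) < 1e-9) - 1]
    l <- layer_of(z1, z2)
    if (is.na(l)) next
    est <- kd$K_d[kd$z_assigned == z2]
    expect_lt(max(abs(est - kdt[, l]) / kdt[, l]), 1e-3)
    checked <- checked + 1
  }
  expect_gte(checked, 4)
})

test_that("transmittance decreases with depth for non-negative attenuation", {
  sc <- default_scenario()
  pr <- generate_irradiance(sc, noise_sd = 0)
  zs <- na.omit(pr$depth)
  tr <- vapply(zs, function(z) sum(transmittance(pr, z)), 0)
  expect_true(all(diff(tr) < 0))
})
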