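test_that("solubility functions are physically ordered and T-monotone", {
  tt <- seq(0, 30, by = 1)
  for (g in c("CO2", "CH4", "N2O", "O2")) {
    k <- vapply(tt, function(t) gas_solubility(g, t), 0)
    expect_true(all(diff(k) < 0))            # warmer water holds less gas
  }
  expect_gt(gas_solubility("CO2", 0), 10 * gas_solubility("CH4", 0))
  # frozen values from an independent evaluation of the published fits
  expect_equal(gas_solubility("CO2", 10), 0.05366131, tolerance = 1e-6)
  expect_equal(gas_solubility("N2O", 10), 0.04016491, tolerance = 1e-6)
  expect_equal(gas_solubility("CH4", 10), 0.00194078, tolerance = 1e-6)
  expect_equal(gas_solubility("O2", 10) * 0.20946 * 1e6, 352.864,
               tolerance = 1e-3)             # umol/kg air-sat oracle
  expect_error(gas_solubility("CO2", 35), "validity")
  expect_error(gas_solubility("CO2", 10, salinity = 5), "S = 0")
})

test_that("an equilibrated bottle is a fixed point of the headspace model", {
  for (g in c("CO2", "CH4", "N2O")) {
    amb <- c(CO2 = 400, CH4 = 1.9, N2O = 0.33)[[g]]
    T_eq <- 15
    C_eq <- gas_solubility(g, T_eq) * amb * 1e-6 * 1e6   # umol/L
    x <- headspace_forward(C_eq, g, ambient_ppm = amb,
                           equilibration_T = T_eq)
    expect_equal(x, amb, tolerance = 1e-12)
    s <- headspace_sample(g, 5, measured_ppm = amb, ambient_ppm = amb,
                          equilibration_T = T_eq, in_situ_T = T_eq)
    inv <- invert_headspace(s)
    expect_equal(inv$concentration, C_eq, tolerance = 1e-12)
    expect_equal(gas_saturation(inv$concentration, g, T_eq, amb), 100,
                 tolerance = 1e-4)
  }
})

test_that("forward-inverse roundtrip is exact over a T x volume x C grid", {
  worst <- 0
  for (g in c("CO2", "CH4", "N2O"))
    for (T_eq in c(4, 10, 20))
      for (Vw in c(1, 2))
        for (Vh in c(10, 20, 60))
          for (C0 in c(0.05, 1, 20, 500)) {
            amb <- c(CO2 = 400, CH4 = 1.9, N2O = 0.33)[[g]]
            x <- headspace_forward(C0, g, amb, T_eq, Vw, Vh)
            s <- headspace_sample(g, 5, x, amb, T_eq, in_situ_T = 4,
                                  water_volume = Vw, headspace_volume = Vh)
            C_hat <- invert_headspace(s)$concentration
            worst <- max(worst, abs(C_hat - C0) / C0)
          }
  expect_lt(worst, 1e-6)
})

test_that("halving the water volume doubles the headspace-derived excess", {
  g <- "CO2"; amb <- 400; T_eq <- 15
  x_meas <- 900
  dissolved <- gas_solubility(g, T_eq) * x_meas * 1e-6 * 1e6
  s2 <- headspace_sample(g, 5, x_meas, amb, T_eq, 4, water_volume = 2)
  s1 <- headspace_sample(g, 5, x_meas, amb, T_eq, 4, water_volume = 1)
  e2 <- invert_headspace(s2)$concentration - dissolved
  e1 <- invert_headspace(s1)$concentration - dissolved
  expect_equal(e1, 2 * e2, tolerance = 1e-12)
})

test_that("larger headspace pulls the measured mixing ratio toward ambient", {
  amb <- 1.9
  C0 <- 5   # strongly supersaturated CH4
  x1 <- headspace_forward(C0, "CH4", amb, 15, headspace_volume = 20)
  x2 <- headspace_forward(C0, "CH4", amb, 15, headspace_volume = 40)
  expect_gt(x1, amb)
  expect_lt(abs(x2 - amb), abs(x1 - amb))
})

test_that("saturation maps concentrations to percent of air equilibrium", {
  C_eq <- gas_solubility("CH4", 3) * 1.9e-6 * 1e6
  expect_equal(gas_saturation(C_eq, "CH4", 3, 1.9), 100)
  expect_equal(gas_saturation(0, "CH4", 3, 1.9), 0)
  expect_equal(gas_saturation(3550 * C_eq, "CH4", 3, 1.9), 355000)
})

test_that("areal storage integrates trapezoidally with constant extension", {
  expect_equal(as.numeric(column_storage(c(2, 9), c(1, 1), 2, 9)), 7)
  # linear 0 -> 2 umol/L across 2-9 m: mean 1 over 7 m
  expect_equal(as.numeric(column_storage(c(2, 9), c(0, 2), 2, 9)), 7)
  # additivity over profiles
  set.seed(5)
  z <- sort(runif(8, 2, 9)); p1 <- runif(8); p2 <- runif(8)
  expect_equal(as.numeric(column_storage(z, p1 + p2, 2, 9)),
               as.numeric(column_storage(z, p1, 2, 9)) +
                 as.numeric(column_storage(z, p2, 2, 9)),
               tolerance = 1e-12)
  # constant extension beyond the sampled range, flagged
  s <- column_storage(c(3, 8), c(2, 2), 2, 9)
  expect_equal(as.numeric(s), 14)
  expect_true(attr(s, "extended"))
  expect_error(column_storage(c(2, 9), c(1, 1), 9, 2), "exceed")
})

test_that("trapezoid storage matches a fine-grid Riemann oracle", {
  f <- function(z) 3 + 2 * sin(z / 2) + 0.3 * z
  z <- seq(2, 9, by = 0.25)
  est <- as.numeric(column_storage(z, f(z), 2, 9))
  zf <- seq(2, 9, length.out = 2e5)
  oracle <- sum(f(zf[-1] / 2 + zf[-length(zf)] / 2) * diff(zf))
  expect_lt(abs(est - oracle) / oracle, 1e-3)
})

test_that("storage change reports the percent difference between dates", {
  z <- 2:9
  p <- rep(4, 8)
  expect_equal(storage_change(z, p, z, p, 2, 9), 0)
  expect_equal(storage_change(z, p, z, p / 2, 2, 9), -50)
  # generator truth: the synthetic July profiles are built with the
  # scenario's imposed storage changes
  sc <- default_scenario()
  tj <- true_gas_profiles(sc, "june")
  tl <- true_gas_profiles(sc, "july")
  for (g in c("CO2", "CH4", "N2O", "O2")) {
    a <- tj[tj$gas == g, ]; b <- tl[tl$gas == g, ]
    expect_equal(storage_change(a$depth, a$concentration,
                                b$depth, b$concentration, 2, 9),
                 sc$gas_summer_change[[g]], tolerance = 1e-9)
  }
})
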