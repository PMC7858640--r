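make_eem <- function(value = 1, corrections = character(),
                     ex = seq(250, 450, 10), em = seq(300, 560, 2)) {
  eem(ex, em, matrix(value, length(em), length(ex)),
      corrections = corrections)
}

test_that("correction steps enforce their fixed order", {
  x <- make_eem()
  blank <- make_eem(0.1)
  abs0 <- absorbance_spectrum(200:800, rep(0, 601), null_corrected = TRUE)
  expect_error(inner_filter_correct(x, abs0), "requires prior")
  expect_error(excise_scatter(x), "requires prior")
  expect_error(raman_normalize(x, blank), "requires prior")
  x1 <- blank_subtract(x, blank)
  expect_equal(x1$corrections, "blank")
  expect_error(blank_subtract(x1, blank), "already")
  x2 <- inner_filter_correct(x1, abs0)
  x3 <- excise_scatter(x2)
  x4 <- raman_normalize(x3, blank)
  expect_equal(x4$corrections,
               c("blank", "inner_filter", "scatter", "raman"))
  expect_error(eem(seq(250, 450, 10), seq(300, 560, 2),
                   matrix(1, 131, 21), corrections = c("scatter", "blank")),
               "out of order")
})

test_that("inner-filter correction applies the absorbance-based factor", {
  x <- make_eem(1, corrections = "blank")
  abs0 <- absorbance_spectrum(200:800, rep(0, 601), null_corrected = TRUE)
  expect_equal(inner_filter_correct(x, abs0)$intensity, x$intensity)
  # A = 0.2 at 1 cm everywhere: factor 10^((0.2+0.2)/2) = 10^0.2
  abs2 <- absorbance_spectrum(200:800, rep(0.2 * 10, 601),
                              pathlength = 0.10, null_corrected = TRUE)
  y <- inner_filter_correct(x, abs2)
  expect_equal(unique(as.vector(y$intensity)), 10^0.2, tolerance = 1e-12)
  # commutes with scalar intensity scaling
  x5 <- make_eem(5, corrections = "blank")
  y5 <- inner_filter_correct(x5, abs2)
  expect_equal(y5$intensity, 5 * y$intensity)
  # unreliable correction warns
  absbig <- absorbance_spectrum(200:800, rep(20, 601), pathlength = 0.10,
                                null_corrected = TRUE)
  expect_warning(inner_filter_correct(x, absbig), "unreliable")
})

test_that("scatter excision masks the generator's ridges and nothing else", {
  sc <- small_eem_scenario()
  clean <- generate_eems(sc, scatter = FALSE, noise_sd = 0)
  ridged <- generate_eems(sc, scatter = TRUE, noise_sd = 0)
  x <- excise_scatter(ridged$eems[[1]])
  ex_g <- matrix(x$ex, length(x$em), length(x$ex), byrow = TRUE)
  em_g <- matrix(x$em, length(x$em), length(x$ex))
  on_ridge <- abs(em_g - ex_g) <= 15 | abs(em_g - 2 * ex_g) <= 15 |
    abs(em_g - 1 / (1 / ex_g - 3382e-7)) <= 5
  expect_true(all(is.na(x$intensity[on_ridge])))
  expect_true(all(!is.na(x$intensity[!on_ridge])))
  # off-ridge cells untouched
  expect_equal(x$intensity[!on_ridge],
               ridged$eems[[1]]$intensity[!on_ridge])
  # masking is idempotent
  x2 <- excise_scatter(x)
  expect_identical(x2$intensity, x$intensity)
  expect_identical(x2$corrections, x$corrections)
  # zero widths mask only exact coincidence cells
  y <- excise_scatter(ridged$eems[[2]], w1 = 0, w2 = 0, w_raman = 0)
  expect_true(all(is.na(y$intensity[em_g == ex_g])))
  expect_true(all(!is.na(y$intensity[em_g == ex_g + 2])))
})

test_that("Raman normalization divides by the blank peak area, gain-free", {
  sc <- small_eem_scenario()
  eg <- generate_eems(sc, scatter = FALSE, noise_sd = 0)
  blank <- eg$blank
  x <- excise_scatter(eg$eems[[1]], w1 = 0, w2 = 0, w_raman = 0)
  area <- raman_area(blank)
  y <- raman_normalize(x, blank)
  expect_equal(y$intensity, x$intensity / area)
  # doubling the blank halves the result
  blank2 <- blank; blank2$intensity <- 2 * blank2$intensity
  y2 <- raman_normalize(x, blank2)
  expect_equal(y2$intensity, y$intensity / 2)
  # common instrument gain on sample and blank cancels
  xg <- x; xg$intensity <- 7 * xg$intensity
  blankg <- blank; blankg$intensity <- 7 * blankg$intensity
  yg <- raman_normalize(xg, blankg)
  expect_equal(yg$intensity, y$intensity, tolerance = 1e-12)
  # blank self-normalization has unit Raman area
  bn <- blank
  bn$intensity <- bn$intensity / raman_area(blank)
  expect_equal(raman_area(bn), 1, tolerance = 1e-12)
})

test_that("fluorescence index is the 450/500 emission ratio at ex 370", {
  ex <- seq(250, 450, 10); em <- seq(300, 560, 2)
  M <- matrix(1.2, length(em), length(ex))
  M[em == 450, ] <- 1.8
  x <- eem(ex, em, M)
  expect_equal(fluorescence_index(x), 1.5)
  expect_equal(fluorescence_index(make_eem(2)), 1)
  # invariant under Raman normalization (a pure ratio)
  xr <- x; xr$intensity <- x$intensity / 3.7
  expect_equal(fluorescence_index(xr), fluorescence_index(x))
  # interpolation between excitation neighbours when 370 nm is absent
  ex2 <- seq(250, 450, 20)   # contains 350, 370 missing
  M2 <- matrix(1, length(em), length(ex2))
  M2[em == 450, ] <- 2
  expect_equal(fluorescence_index(eem(ex2, em, M2)), 2)
  bad <- make_eem(0)
  expect_warning(fi <- fluorescence_index(bad), "undefined")
  expect_true(is.na(fi))
})
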