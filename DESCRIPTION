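Package: underice
Title: Under-Ice Water-Column Analysis for Polar Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing the water column of ice-covered lakes:
    freshwater density and Brunt-Vaisala stability from CTD profiles with
    stratification-layer detection; spectral diffuse attenuation
    coefficients, transmittance, reflectance and band energies from
    irradiance profiles; CDOM absorption coefficients, spectral slopes,
    SUVA254 and an in-situ absorption budget partitioned among water, CDOM,
    phytoplankton and non-algal particles; excitation-emission matrix
    correction and non-negative PARAFAC decomposition of fluorescent
    dissolved organic matter; dissolved greenhouse-gas concentrations from
    headspace equilibration with saturation and areal storage integrals;
    areal pigment stocks and compositional (additive log-ratio) statistics.
    Includes a synthetic-lake generator with known ground truth so every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
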