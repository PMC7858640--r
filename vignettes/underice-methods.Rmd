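---
title: "Methods: models, conventions and design choices in underice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in underice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(underice)
```

`underice` implements the quantitative chain used to describe the water
column of an ice-covered lake: density and stability from CTD profiles,
apparent optical properties from spectral irradiance, CDOM absorption and
fluorescence characterization, dissolved greenhouse gases from headspace
equilibration, and areal stock integrals. This vignette records the models
behind each stage, the parameters that matter, and the design decisions
that were genuinely open, so that a user can judge what the package's
passing tests do and do not demonstrate.

## Density, stability and layer structure

Density uses a freshwater (Chen–Millero-type) equation of state: a
sixth-order polynomial in temperature for pure water — maximum
999.972 kg m⁻³ near 3.98 °C — plus a linear haline contraction term
`(0.8181 − 3.85e−3 T + 4.96e−5 T²) · S`. No pressure term is included:
the package targets shallow lakes (tens of metres at most), where the
compressibility contribution is far below the signal of interest. The
exact polynomial coefficients a given field study used are rarely
published; ours are documented in `water_density()` and verified in the
tests against independent evaluations, but are not claimed to match any
specific toolbox bit-for-bit.

Salinity is not measured directly in dilute lakes; it is derived from
specific conductance at 25 °C by a linear factor computed from a
major-ion template (`default_ion_template()`: a Ca²⁺/HCO₃⁻-dominated
composition, fractions configurable). The practical salinity scale was
deliberately not used — it is calibrated for seawater ion ratios and
misbehaves below ~2 g/kg. The default template gives
k ≈ 6.56 × 10⁻⁴ g/kg per µS/cm.

The buoyancy frequency is computed exactly as the field convention for
these lakes states it: `N² = g (Δρ/Δz) / ρ̄` with `g = 9.8 m s⁻²` and
`ρ̄` fixed at the maximum density of pure water, 1000 kg m⁻³, rather than
a local mean density. The deviation from using the local mean is below
0.03 % and reproducing the conventional form verbatim makes results
comparable with published profiles. `N²` is reported **signed**:
convectively unstable strata (negative `N²`) are a finding, not an error,
and are never clamped; `N` is flagged undefined there.

`detect_layers()` segments the profile into the canonical under-ice
structure — stable boundary layer below the ice, convective cell, stable
bottom layer — as contiguous runs of segments with `N² ≥ threshold`. The
threshold default is `5e−5 s⁻²`; no published value exists for this
segmentation, so the parameter is exposed in the configuration and the
default was chosen once as a value that separates clearly stratified from
effectively neutral strata in dilute lakes. Degenerate profiles (all
stable, all neutral, too short) return an explicit `resolved = FALSE`
with the layout described, never a silent guess.

## Apparent optical properties

Transmittance is relative to the incident spectrum **in air**;
reflectance is `E_u/E_d` at one depth. Band energies are **discrete
sums** of spectral irradiance over the 1 nm grid, not trapezoids,
matching how broadband energy is conventionally reported for these
profiles; on the 278–720 nm grid a flat 1 mW m⁻² nm⁻¹ spectrum gives
TOTAL = 443 mW m⁻². The UVR band is 278–399 nm and PAR 400–700 nm:
400 nm is assigned to PAR only, so the two bands never double-count a
grid point. The lower UVR bound is the instrument grid bound, not a
physiological definition.

`K_d` between adjacent records is `−ln(E₂/E₁)/(z₂−z₁)`, assigned to the
lower depth `z₂`. The air → first-underwater pair is flagged *apparent*:
it folds in reflection at the ice surface and is not a water-column
property. Broadband (e.g. PAR) attenuation is computed from
band-integrated energies, not as a mean of spectral `K_d` — this is the
convention under which published broadband attenuation coefficients are
derived, and the two differ for non-flat spectra. Divisions are guarded
by an irradiance floor of 1e−6 of each spectrum's maximum: wavelengths
below the floor are masked rather than producing log-of-noise values.

## CDOM absorption and indices

The spectrophotometric chain keeps the decadic/Napierian distinction
explicit, because the index literature mixes the two:

* the null-point correction subtracts the mean absorbance over
  750–800 nm from the blank-subtracted spectrum (a flag prevents double
  application);
* absorption coefficients are `a = 2.303 A / L` — the conventional
  printed factor 2.303 is used literally rather than `ln 10`, so numbers
  match the index literature to its stated precision;
* `SUVA254` is **decadic** absorbance per metre divided by DOC
  (L mg⁻¹ m⁻¹); `a320` and `a*_CDOM = a320/DOC` use the **Napierian**
  spectrum.

Spectral slopes are windowed log-linear regressions, positive for
spectra decaying with wavelength; the `S289` window is 279–299 nm. The
20 nm window ending at 299 was chosen over a literal "279–289" reading
of some summaries because the index family this slope belongs to uses
20 nm windows; both ends are configurable arguments. A nonlinear
exponential fit was considered and rejected as the default: the cited
index definitions are windowed log-linear slopes, and the two differ in
the presence of offsets. For a single-exponential spectrum the slope
ratio `S_R = S285/S375` is exactly 1, which the tests assert.

The absorption budget partitions measured particulate absorption into
non-algal particles (NAP) and phytoplankton by fitting the standard NAP
exponential `a_NAP(λ) = a_NAP(443) e^(−S_NAP(λ−443))` over windows where
pigment absorption is minimal (380–420 and 600–650 nm, avoiding both the
blue and red chlorophyll bands), then `a_ph = a_part − a_NAP` clipped at
zero with the clip count logged. The total `a_t` is assembled as the sum
of the four components, so closure is exact by construction and asserted.
The bundled pure-water absorption table
(`inst/extdata/water_absorption_synthetic.csv`) is a smooth synthetic
compilation approximating published visible-band pure-water values, as
its header states; users with a preferred published table can pass it
via the `a_w` argument, and no test result depends on the table's exact
values.

## EEM correction and PARAFAC

Corrections apply in a fixed order — blank subtraction, inner-filter
(`10^((A_ex+A_em)/2)` on 1 cm-equivalent decadic absorbance), scatter
excision, Raman normalization — and each step refuses to run out of
order. Scatter handling **masks** cells (first-order Rayleigh within
15 nm of `em = ex`, second order within 15 nm of `em = 2ex`, water Raman
within 5 nm of the 3382 cm⁻¹ line); masked cells are treated as missing
in the decomposition, never interpolated, because interpolation invents
trilinear structure exactly where the model would be fitted to it. The
widths are instrument-dependent defaults, not claims about any original
processing. Raman units divide by the trapezoid area of the blank's
emission scan at ex 350 nm over 371–428 nm; the result is invariant to
the instrument's arbitrary gain provided sample and blank share it.

The PARAFAC fit is a non-negativity-constrained alternating least
squares on the sample × emission × excitation tensor. Each row update is
a small non-negative least-squares problem restricted to the observed
cells; the fast path is the unconstrained normal-equation solution
(valid whenever it is already non-negative), with Lawson–Hanson NNLS as
fallback. Because every block update is an exact constrained minimizer,
the residual sum of squares is non-increasing; this is asserted at every
iteration (with a floating-point slack) rather than assumed. Defaults:
10 random restarts, tolerance 1e−8 on the relative change of the
residual, 2500 iterations maximum, all driven by a single seed so fits
are reproducible; ALS is initialization-sensitive and the restarts are
not optional decoration. After fitting, loadings are peak-normalized
("Fmax scaling") so the score of component k in sample i is the modelled
maximum fluorescence `[Ck]` in Raman units; `%Ck = 100·[Ck]/F_T` and the
additive log-ratio transform (`ln(%Ck/%C_denominator)`) prepares the
compositional percentages for ordination. Zeros are replaced by half the
smallest positive entry before the log, with a warning — the standard
conservative replacement. Component-count diagnostics (split-half, core
consistency) are deliberately not automated; choosing K is a modelling
decision, and reproducing any specific published multi-component model
requires that model's full calibration sample set, which is out of scope.

## Headspace gases

The bottle model is an exact mass balance: the original dissolved amount
equals the post-equilibration dissolved amount (Henry's law at the
equilibration temperature and the measured partial pressure) plus the
net transfer to the headspace (ideal gas law on the measured-minus-
ambient mixing ratio). The same forward model generates synthetic
measurements and is inverted by the analysis, so the roundtrip is exact
to floating point — the tests require < 1e−6 relative over a grid of
temperatures, volumes and concentrations. Defaults follow field
practice: 2 L water, 20 mL ambient-air headspace, near-sea-level
pressure.

Solubility functions are the standard oceanographic temperature fits
(Weiss for CO₂; Wiesenburg & Guinasso's Bunsen-coefficient fit divided
by 22.414 L/mol for CH₄; Weiss & Price for N₂O; the Garcia–Gordon refit
of Benson–Krause for O₂), evaluated at zero salinity — appropriate for
lakes whose solute load is far too dilute to affect solubility
measurably. The data model keeps the equilibration temperature and the
in-situ temperature separate: they genuinely differ in field practice,
Henry's law in the inversion uses the former, and saturation
(`100·C/C_eq`) always uses the latter. No carbonate-system correction is
applied to CO₂: the headspace method measures free CO₂, and DIC
speciation is explicitly out of scope.

Areal storage is a trapezoid over the profile with constant extension
from the outermost samples to the integration bounds (flagged when
used); with µmol/L and metres the integral is directly mmol m⁻².
Constant extension was chosen over linear extrapolation because sparse
two- or three-depth designs make extrapolation unstable, and the same
choice applies to the pigment-stock integral.

## Statistics

Pearson correlation is reported with `df = n − 2` and a two-sided
t-based p; zero-variance inputs return a flagged undefined result. PCA
operates on the column-standardized (correlation-matrix) table, the
appropriate convention for indicator sets with mixed units; variance
fractions sum to 1 and the implementation is cross-checked in the tests
against an independent eigen-decomposition of the correlation matrix.
Compositional blocks must be alr-transformed before entering the PCA
(`alr_spec` does this in one step), since raw percentages are
mathematically dependent.

## The synthetic lake: what it does and does not emulate

`lake_scenario()` fixes the study conditions: a 9.7 m lake under 2 m of
ice; a stable surface layer down to 4 m, a convective cell from 4 to
8 m, and a stable bottom layer below; inverse thermal stratification
(0.5 °C under the ice, 3.2 °C mid-column, 3.9 °C at the bottom, all
below the density maximum so warming with depth stabilizes); specific
conductance rising monotonically 150 → 330 µS/cm with the gradients
confined to the stable layers; oxygen supersaturation (160 %) in the
cell and depletion (50 %) at the bottom; a chlorophyll maximum in the
bottom layer; weakly colored CDOM (a₃₂₀ ≈ 0.5–0.6 m⁻¹, S = 0.018 nm⁻¹)
with a constant absorbance offset to exercise the null-point correction;
three Gaussian EEM fluorophores with uniform positive scores; and
strongly supersaturated gas profiles (bottom-water CH₄ at 355 000 % of
air equilibrium, N₂O at 222 % mid-column, CO₂ at 497 % at depth) whose
July profiles are the June profiles scaled by −50 % (CO₂, CH₄), −19 %
(N₂O) and +32 % (O₂).

Instrument noise is additive Gaussian with per-instrument defaults —
CTD 0.1 % relative, radiometer 2 %, spectrophotometer 0.0005 absorbance
units, fluorometer 1 % of the signal maximum, gas chromatograph 2 % —
chosen once from typical instrument specifications, since field studies
rarely publish their noise floors; all are scenario parameters.

The generator deliberately does **not** simulate convection dynamics
(layers are imposed, not emergent), ice optics beyond a bulk spectral
transmittance, bio-optical feedbacks between chlorophyll and
attenuation, carbonate-system chemistry, or realistic EEM residual
structure beyond Gaussian noise and scatter ridges. Passing recovery
tests therefore demonstrate that the analysis chain inverts its own
forward models correctly at realistic noise levels — they do not
validate the forward models against nature, and real profiles can
violate the generator's assumptions (non-monotone conductance,
non-exponential CDOM, correlated sensor drift) in ways the tests do not
probe.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run the default scenario sizes:
443 wavelengths (278–720 nm), a 0.1 m CTD grid over 2–9.7 m, 20 EEM
samples on a 21 × 131 grid with three components and three PARAFAC
restarts, and a 3 × 3 × 3 × 4 headspace roundtrip grid. These sizes were
chosen as the smallest that exercise every code path at the study's own
dimensions; the PARAFAC restart count in the scripted runs (3, versus
the function default of 10) reflects that recovery on these synthetic
sets is insensitive to further restarts. Key tolerances: `K_d` recovery
< 0.1 % relative at zero noise; slope recovery to 1e−10 on exact
exponentials; Tucker congruence ≥ 0.95 for loading recovery at 1 %
noise; headspace roundtrip < 1e−6 relative; budget closure exact;
compositional row sums exact to 1e−9.

## Known limitations

* The equation of state and solubility fits are valid for 0–30 °C (gas)
  and −2–40 °C (density); polar brines and geothermal inputs are out of
  range.
* `S_NAP` fitting assumes the NAP windows are pigment-free; heavily
  packaged or detrital-dominated samples can bias `a_ph` low.
* The PARAFAC implementation targets the modest tensor sizes of EEM
  work (tens of samples); it is not tuned for hundreds of samples.
* `pca_summary()` refuses constant columns under standardization rather
  than dropping them silently.
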