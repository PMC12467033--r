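---
title: "Models and methods behind enzbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enzbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzbind)
```

`enzbind` chains the standard assays used to characterize a reversible
enzyme inhibitor — activity/IC50, inhibition-type kinetics,
fluorescence-quenching binding analysis, Van't Hoff thermodynamics,
conformational spectroscopy and FTIR secondary structure — into one
tested pipeline. This vignette explains the models, the assumptions they
make, the tunable parameters, and the design choices taken where the
methodology is genuinely open. The running example is a study design of
six porphyrin inhibitors against α-amylase and α-glucosidase, whose
published apparent constants ship with the package
(`kinetic_constants()`, `quench_binding_constants()`).

## Activity and IC50

The plate arithmetic is exact: inhibition
$\mathrm{inh} = (1 - (A_1-A_2)/(A_3-A_4))\cdot 100$ with a sample
control $A_2$ (enzyme replaced by buffer) and a blank pair $A_3, A_4$;
MTT viability $(A_s-A_b)/(A_c-A_b)\cdot 100$. Both are affine in the
sample absorbance and may legitimately leave $[0, 100]$.

`estimate_ic50()` defaults to linear interpolation between the two
points bracketing 50% — assumption-free and faithful to the common
"linear regression" reporting of plate IC50s. The four-parameter
logistic $y = b + (t-b)/(1+(\mathrm{IC50}/c)^h)$ is offered alongside;
it adds asymptote parameters and therefore needs a dose design that
spans them. The noise-robustness test uses 9 doses over a 256-fold range
centred on the IC50 with triplicate wells averaged, which is the
standard 4PL plate design; sparser single-well designs carry visibly
more variance in the midpoint.

Reversibility (`reversibility_verdict()`) fits $v = a + b[E]$ per
inhibitor concentration: reversible inhibition requires lines through
the origin (|intercept| within `origin_tolerance`, default 5% of the
maximum velocity — the classical plots assert origin intersection
without a tolerance, so one must be chosen) and slopes strictly
decreasing with inhibitor.

## Inhibition kinetics

Each substrate series is fitted as apparent Michaelis–Menten. The
default mode is the double-reciprocal (Lineweaver–Burk) OLS of $1/v$ on
$1/[S]$, matching how such studies are analysed and reported; the direct
nonlinear fit is available for robustness comparison (the two agree to
$10^{-6}$ relative on clean data, and the nonlinear mode weights
low-velocity points less aggressively under noise).

Classification combines two signals:

* **Trends** across inhibitor concentrations: Km constant (relative
  spread ≤ `tol`, default 5%) with Vmax strictly decreasing is
  non-competitive; Km rising with Vmax falling is mixed; Km rising with
  Vmax constant is competitive; both falling with constant Km/Vmax is
  uncompetitive. The 5% default separates the observed regimes cleanly:
  the shipped non-competitive system varies Km by ~1% while the mixed
  systems rise by 40%+.
* **Geometry**: the centroid of all pairwise Lineweaver–Burk line
  intersections. Mixed-type lines meet at
  $x^* = -K_i/(K_m K_{is})$, $y^* = (1-K_i/K_{is})/V_{max}$ — the second
  quadrant when $K_i < K_{is}$ — while non-competitive lines meet on the
  negative x-axis at $-1/K_m$. A single intersection is what one reads
  off a plot; the centroid with its dispersion is the reproducible
  version of that reading.

If the two signals disagree the result is labelled `ambiguous` and
carries both; there is no silent choice.

Ki and Kis come from the secondary plots: the LB slope
$K_m/V_{max}\,(1 + [I]/K_i)$ regressed on $[I]$ gives
$K_i = \text{intercept}/\text{slope}$, and the LB y-intercept
$1/V_{max}\,(1+[I]/K_{is})$ likewise gives $K_{is}$. Both use the
secondary regression's own intercept rather than the measured $[I]=0$
value: with tabulated constants rounded to four decimals, the regression
intercept is what reproduces the published Ki values (to 0.1–1%), while
anchoring on the single $[I]=0$ row does not. Unweighted OLS is used
throughout; the weighting of the original regressions is not stated, and
unweighted reproduces the published constants within 1%.

```{r}
fits <- kinetic_fits_from_table(kinetic_constants("alpha_amylase", "TAPP"))
classify_inhibition(fits)
estimate_ki(fits)
```

## Fluorescence quenching and binding

Inner-filter correction is applied first:
$F_{cor} = F_{obs}\,e^{(A_{ex}+A_{em})/2}$, to every point including the
$[Q]=0$ reference (whether the original workflows corrected the
reference is typically unstated; correcting all points keeps $F_0/F$
consistent when absorbances are flat and is exactly invertible against
the synthetic generator). After correction the stored absorbances are
zeroed, making the operation idempotent.

`stern_volmer_fit()` fits both the linear law $F_0/F = 1 + K_{SV}[Q]$
and the exponential variant $F_0/F = e^{K_{SV}[Q]}$ — the form used in
practice when the plot curves upward, signalling concurrent static and
dynamic quenching. Model selection is by residual sum of squares with a
5% minimum-improvement guard so that noise cannot flip clean linear data
to the exponential branch (visual curvature judgement, made
reproducible). The linear RSS is floored at $10^{-20}\sum (F_0/F)^2$ so
exactly-linear data score zero curvature rather than a $0/0$ artifact.

Mechanism classification uses the standard temperature logic:
$K_{SV}$ decreasing with temperature and
$K_q = K_{SV}/\tau_0$ above the diffusional ceiling (default threshold
$2\times10^{10}$ L/mol/s, fluorophore lifetime $\tau_0 = 10^{-8}$ s,
both configurable) is static quenching; the opposite trend or a
diffusion-compatible $K_q$ is dynamic; the static signature with an
exponential plot at any temperature is mixed-static-dominant.

Binding constants come from the double-log plot
$\log_{10}[(F_0-F)/F] = \log_{10}K_a + n\log_{10}[Q]$ (base 10, the
plotting convention of this literature). $K_a$ in L/mol requires molar
quencher concentrations; `convert_concentration()` bridges the µg/mL
dosing scale via a molecular-weight registry. The registry values for
the six porphyrins are computed from their molecular formulas (TAPP
C44H34N8 = 674.8, THPP C44H30N4O4 = 678.8, TCPP C48H30N4O8 = 790.8,
M–TCPP = TCPP − 2H + metal), since studies report Ka in molar units
without printing the conversion; the registry is user-overridable.

## Van't Hoff thermodynamics

$\ln K_a$ regressed on $1/T$ gives $\Delta H^0 = -R\cdot\text{slope}$
and $\Delta S^0 = R\cdot\text{intercept}$ — the intercept method. The
alternative $(ΔH-ΔG)/T$ route gives different entropy values on
non-collinear data and does not reproduce published tables, so it is not
used. $\Delta G^0$ is reported per temperature as $-RT\ln K_a$, which
matches published values to three figures; the $\Delta H^0 - T\Delta
S^0$ variant is attached as a consistency diagnostic (the two coincide
exactly on Van't Hoff-consistent data).

Force classification follows the strict sign rules: both positive →
hydrophobic; both negative → hydrogen bond / van der Waals; $\Delta H^0
< 0, \Delta S^0 > 0$ → electrostatic. The fourth quadrant has no rule in
this scheme and is labelled `out_of_ruleset`; magnitudes below a
configurable epsilon are labelled `boundary` with a warning rather than
forced into a class, because the rules are defined for strict signs
only.

Note one asymmetry worth knowing: rescaling every $K_a$ by a common
factor (a unit change) shifts $\Delta S^0$ by $R\ln(\text{factor})$ but
leaves $\Delta H^0$ untouched — thermodynamic parameters from binding
constants are unit-sensitive in entropy only.

## Conformational spectroscopy

Synchronous spectra at Δλ = 15 nm report tyrosine and at Δλ = 60 nm
tryptophan microenvironments (the standard attribution).
`rsfq()` computes $1 - F/F_0$ from peak intensities — peak intensity,
not integrated area, since band areas change shape under shifts and the
published curves are peak-read. `residue_contribution()` calls Trp or
Tyr dominance when one channel's RSFQ exceeds the other at a strict
majority of concentrations.

Peak positions use parabolic interpolation around the discrete maximum,
so sub-grid shifts are detectable; the shift threshold defaults to one
grid step (spectra are typically recorded on 1–4 nm grids and published
shifts are read at that resolution). Ties in a flat-topped maximum break
toward shorter wavelength.

EEM peak picking masks the first-order Rayleigh ridge
($|Em - Ex| \le$ half-width) and its second order ($|Em - 2Ex|$),
default half-width 15 nm, then returns 8-neighbourhood local maxima
above a prominence floor (default 5% of the unmasked maximum). Both
defaults are standard EEM practice rather than taken from any specific
instrument; they are arguments, not constants.

## FTIR amide-I deconvolution

The amide-I band (1600–1700 cm⁻¹) is windowed and a straight baseline
through the window endpoints subtracted; small negative residuals are
clipped with a count kept. Sub-bands are Gaussian — the dominant
convention for amide-I curve fitting — fitted as a bounded Gaussian sum
by Levenberg–Marquardt. Two seedings: negative minima of the
Savitzky–Golay second derivative (window 9 points, order 3,
configurable), or one candidate per class range. Class ranges:
β-sheet 1615–1637, antiparallel β-sheet 1638–1648, α-helix 1649–1660,
β-turn 1661–1680, random coil 1681–1692 cm⁻¹; the 1 cm⁻¹ gaps between
printed ranges are closed left, so a centre at 1637.5 is β-sheet and
1638.0 is antiparallel — a deterministic boundary convention asserted by
test. Centres outside all ranges are excluded from the percentage
denominator with a warning.

```{r}
fr <- c(alpha_helix = 24.58, beta_sheet = 27.34, beta_turn = 23.64,
        random_coil = 14.10, beta_antiparallel = 10.34)
sp <- gen_ftir_spectrum(fr)
assign_structure(deconvolve(extract_amide_I(sp), seeding = "fixed_classes"))
```

## The synthetic-data generators

Every stage has a generator whose zero-noise output its analysis inverts
exactly (relative error ≤ 1e-9; FTIR class areas within 3 percentage
points, the residual being genuine band overlap). Design choices:

* Noise is additive Gaussian on velocities, intensities and absorbances.
  Replicate data in this field are reported as mean ± sd with no
  distributional claim, and additive Gaussian is the simplest model that
  supports recovery testing. Noise magnitudes are arguments with zero
  defaults, since replicate-level noise is rarely published.
* The kinetics generator uses the two-constant rate law
  $v = V_{max}[S] / (K_m(1+[I]/K_i) + [S](1+[I]/K_{is}))$, algebraically
  the standard mixed-inhibition model in direct (not double-reciprocal)
  form; the other three types are its limits.
* The FTIR generator defaults to σ = 5 cm⁻¹ sub-bands (FWHM ≈ 11.8,
  realistic for amide-I components) with centres near each class-range
  midpoint. The width matters: components must be effectively supported
  inside the 1600–1700 window, because the endpoint-anchored baseline
  removes whatever leaks past the edges, and a band centred at 1686.5
  with σ = 6 already loses enough tail beyond 1700 to distort
  neighbouring class areas by several points. The generator documents
  this constraint rather than silently widening the window.
* The quench generator can attenuate its output by
  $e^{-(A_{ex}+A_{em})/2}$ so the inner-filter correction is tested as
  an exact inverse pair.
* One integer seed per generated dataset; with `noise_sd = 0` the output
  is independent of the seed.

What the generators do **not** emulate: instrument drift,
photobleaching, pH/thermal denaturation kinetics, scattering backgrounds
beyond an idealized Rayleigh ridge, or correlated replicate error.
Passing the inverse-pair suites therefore demonstrates correctness of
the estimators' algebra and numerics, not robustness to every artifact
of real spectra.

## Problem sizes and numerical choices

The test suite runs entirely on small problems: 4-point substrate
series over 6 inhibitor concentrations, 5–8-point titrations, 3-point
temperature series, 201-point FTIR windows, 200-seed noise sweeps for
the IC50 robustness property — a few seconds in total, by construction:
these are the assay sizes the methods are designed for.

Nonlinear fits (`minpack.lm`) run with tight tolerances
(`ftol`/`ptol` ≈ 1e-14, generous iteration caps) so that zero-noise
inverse pairs reach 1e-9 relative recovery rather than stalling at
optimizer defaults; amide-I sums additionally bound centres to the
window and drop collapsed (zero-amplitude) components. Secondary
regressions and all linearized fits are plain `stats::lm`.

## Known limitations

* The Lineweaver–Burk route inherits the classical bias of
  double-reciprocal weighting under noise; the nonlinear mode is the
  remedy and the two are cross-checked on clean data.
* IC50 interpolation requires the data to bracket 50%; monotone but
  sub-50% curves are a hard error, not an extrapolation.
* The exponential Stern–Volmer form is used as printed in this
  literature (no additive 1); its Ksv is comparable to the linear one
  only at small $K_{SV}[Q]$.
* Published-table recomputation is limited by table rounding (4
  decimals): agreement is 0.1–1% for Ki/ΔH/ΔS, not machine precision.
* Tight-binding (Morrison) kinetics, heat-capacity-corrected Van't Hoff,
  PARAFAC EEM decomposition and Fourier self-deconvolution are out of
  scope.
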