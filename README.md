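# enzbind

Characterizing how a small molecule inhibits an enzyme takes a chain of
bench assays — dose–response plates, Lineweaver–Burk kinetics,
fluorescence-quenching titrations, Van't Hoff thermodynamics, synchronous
and 3-D fluorescence scans, and FTIR secondary-structure analysis — each
with its own arithmetic and its own diagnostic rules. `enzbind` implements
that whole chain as a set of small, classed model fits in base R, so a
study of, say, porphyrin inhibitors of the digestive enzymes α-amylase and
α-glucosidase can go from raw CSV tables to inhibition constants, binding
thermodynamics and conformational metrics reproducibly.

It is written for enzymologists and food/pharma chemists who run these
assays, and for anyone who wants to audit such an analysis.

## What it computes

* **Activity**: inhibition rate `(1 − (A₁−A₂)/(A₃−A₄))·100`, MTT cell
  viability, IC50 by bracketing interpolation or a four-parameter
  logistic fit, reversibility verdicts from velocity-vs-enzyme lines, and
  temperature/pH stability profiles.
* **Inhibition kinetics**: apparent Km/Vmax per inhibitor concentration
  (double-reciprocal OLS of `1/v` on `1/[S]`, or direct nonlinear fit of
  `v = Vmax[S]/(Km+[S])`), inhibition-type classification from Km/Vmax
  trends plus Lineweaver–Burk line geometry, and the inhibition constants
  from secondary plots: `slope = Km/Vmax + Km[I]/(Vmax·Ki)` gives Ki,
  `intercept = 1/Vmax + [I]/(Vmax·Kis)` gives Kis.
* **Quenching and binding**: inner-filter correction
  `F_cor = F_obs·e^{(A_ex+A_em)/2}`, Stern–Volmer fits
  (`F₀/F = 1 + K_SV[Q]` and the exponential variant for upward-curved
  plots), `K_q = K_SV/τ₀`, mechanism classification
  (static / dynamic / mixed-static-dominant), and the double-log plot
  `log[(F₀−F)/F] = log K_a + n·log[Q]` for the binding constant and site
  number.
* **Thermodynamics**: Van't Hoff regression
  `ln K_a = −ΔH⁰/(RT) + ΔS⁰/R`, per-temperature `ΔG⁰ = −RT ln K_a`, and
  binding-force classification from the signs of ΔH⁰ and ΔS⁰.
* **Conformation**: RSFQ (`1 − F/F₀`) per synchronous channel,
  tyrosine-vs-tryptophan dominance, sub-grid peak-shift detection, and
  EEM peak picking with Rayleigh-scatter masking.
* **FTIR**: amide-I (1600–1700 cm⁻¹) windowing with endpoint baseline,
  Gaussian-sum deconvolution (second-derivative or fixed-class seeding),
  and secondary-structure percentages by wavenumber-class assignment.
* **Synthetic data**: a generator per stage with known ground truth, so
  every fit can be tested as an exact inverse at zero noise.

## Worked example

Published apparent kinetic constants for six porphyrin inhibitors ship
with the package. Recomputing the α-amylase–TAPP inhibition constants:

```r
library(enzbind)
fits <- kinetic_fits_from_table(kinetic_constants("alpha_amylase", "TAPP"))
classify_inhibition(fits)
#> Inhibition type: mixed
#>   trend: mixed (Km spread 46.2%, Vmax spread 31.9%)
#>   LB intersection centroid (-0.1051, 3.19), second_quadrant
estimate_ki(fits)
#> Ki = 8.7116 ug/mL  (secondary plot R^2 = 1.0000)
estimate_kis(fits)
#> Kis = 21.1006 ug/mL  (secondary plot R^2 = 0.9982)
```

A mixed-type verdict (Km rises, Vmax falls, lines meet in the second
quadrant) with Ki < Kis: TAPP binds free α-amylase more tightly than the
enzyme–substrate complex. The thermodynamic side, from the shipped
binding constants for α-glucosidase–THPP:

```r
tb <- quench_binding_constants("alpha_glucosidase", "THPP")
vant_hoff_fit(data.frame(temperature_k = tb$temperature_k,
                         ka_l_per_mol = tb$ka_1e5_l_per_mol * 1e5))
#> Van't Hoff analysis
#>   dH = -97.15 kJ/mol, dS = -207.19 J/mol/K  (R^2 = 0.9924)
#>   dG(298 K) = -35.31 kJ/mol
#>   dG(304 K) = -34.36 kJ/mol
#>   dG(310 K) = -32.82 kJ/mol
#>   dominant force: hbond_vdw
```

Negative ΔH⁰ and ΔS⁰ classify the binding as hydrogen-bond / van der
Waals driven; ΔG⁰ < 0 at all three temperatures means spontaneous
complex formation.

A thin CLI over the same functions is installed at
`system.file("exec", "enzbind", package = "enzbind")` with subcommands
`kinetics`, `quench`, `thermo`, `activity`, `ftir` and `simulate`.

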