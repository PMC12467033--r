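#' Synthetic assay data with known ground truth
#'
#' Every analysis stage has a paired generator so that
#' `analysis(generator(theta))` recovers `theta` exactly at zero noise.
#' Noise is additive Gaussian (matching mean +/- sd replicate reporting);
#' a single integer seed fixes each generated dataset.
#'
#' @name synthetic-data
NULL

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Generate inhibited Michaelis-Menten kinetic series
#'
#' Velocities follow the two-constant rate law
#' `v = Vmax [S] / (Km (1 + [I]/Ki) + [S] (1 + [I]/Kis))`, which covers
#' all four classical inhibition types: `competitive` (the `[S]` factor
#' drops, `Kis -> Inf`), `uncompetitive` (the `Km` factor drops,
#' `Ki -> Inf`), `noncompetitive` (`Kis = Ki`) and `mixed` (both
#' constants).
#'
#' @param km,vmax True Michaelis constant (mmol/L) and maximum velocity
#'   (dOD/min); positive.
#' @param type Inhibition type.
#' @param ki Free-enzyme inhibition constant, ug/mL (ignored for
#'   `uncompetitive`).
#' @param kis Complex inhibition constant, ug/mL (only used for `mixed`;
#'   `noncompetitive` uses `ki`, the others none).
#' @param substrate_grid Substrate concentrations, mmol/L.
#' @param inhibitor_grid Inhibitor concentrations, ug/mL.
#' @param noise_sd Gaussian noise sd on velocities; default 0.
#' @param seed Optional integer seed.
#' @return List of [kinetic_series()], one per inhibitor concentration.
#' @export
#' @examples
#' gen_kinetics(3.9047, 0.1826, "mixed", ki = 8.7057, kis = 21.2847,
#'              substrate_grid = c(2.5, 5, 7.5, 10),
#'              inhibitor_grid = c(0, 2, 4))
gen_kinetics <- function(km, vmax,
                         type = c("mixed", "competitive", "noncompetitive",
                                  "uncompetitive"),
                         ki = NULL, kis = NULL,
                         substrate_grid, inhibitor_grid,
                         noise_sd = 0, seed = NULL) {
  type <- match.arg(type)
  if (km <= 0 || vmax <= 0) stop("Km and Vmax must be positive")
  if (!length(substrate_grid) || !length(inhibitor_grid))
    stop("substrate and inhibitor grids must be non-empty")
  needs_ki <- type != "uncompetitive"
  if (needs_ki && (is.null(ki) || ki <= 0))
    stop("ki must be positive for this inhibition type")
  if (type == "mixed" && (is.null(kis) || kis <= 0))
    stop("kis must be positive for mixed inhibition")
  a_ki <- switch(type, competitive = ki, mixed = ki,
                 noncompetitive = ki, uncompetitive = Inf)
  a_kis <- switch(type, competitive = Inf, mixed = kis,
                  noncompetitive = ki, uncompetitive = ki)
  maybe_seed(seed)
  lapply(inhibitor_grid, function(I) {
    v <- vmax * substrate_grid /
      (km * (1 + I / a_ki) + substrate_grid * (1 + I / a_kis))
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    kinetic_series(I, substrate_grid, v)
  })
}

#' Generate a fluorescence quench titration
#'
#' Exactly one binding/quenching model must be supplied: `ksv` for the
#' linear Stern-Volmer law `F = F0 / (1 + Ksv [Q])`, or `(ka, n)` for the
#' double-log binding model `(F0 - F)/F = Ka [Q]^n`.  When `inner_filter`
#' absorbances are given, the emitted intensities are attenuated as
#' `Fobs = F exp(-(Aex + Aem)/2)` so that [inner_filter_correct()]
#' inverts the attenuation exactly.
#'
#' @param F0 Unquenched intensity (> 0).
#' @param Q_grid Quencher concentrations, mol/L, starting at 0.
#' @param temperature Temperature, K.
#' @param ksv Stern-Volmer constant, L/mol (linear mode).
#' @param ka,n Binding constant (L/mol) and site number (binding mode).
#' @param inner_filter Optional list with vectors `Aex` and `Aem` (or
#'   scalars, recycled).
#' @param noise_sd Gaussian noise sd on intensities; default 0.
#' @param seed Optional integer seed.
#' @return A [quench_titration()].
#' @export
#' @examples
#' gen_quench_titration(100, c(0, 1e-6, 2e-6, 4e-6, 8e-6), 298, ka = 1e5, n = 1)
gen_quench_titration <- function(F0, Q_grid, temperature = 298,
                                 ksv = NULL, ka = NULL, n = NULL,
                                 inner_filter = NULL, noise_sd = 0,
                                 seed = NULL) {
  if (F0 <= 0) stop("F0 must be positive")
  ksv_mode <- !is.null(ksv)
  ka_mode <- !is.null(ka) && !is.null(n)
  if (ksv_mode == ka_mode)
    stop("supply exactly one model: ksv, or (ka, n)")
  Fq <- if (ksv_mode) F0 / (1 + ksv * Q_grid)
        else F0 / (1 + ka * Q_grid^n)
  maybe_seed(seed)
  if (noise_sd > 0) Fq <- Fq + stats::rnorm(length(Fq), 0, noise_sd)
  Aex <- Aem <- NULL
  if (!is.null(inner_filter)) {
    Aex <- rep_len(inner_filter$Aex, length(Q_grid))
    Aem <- rep_len(inner_filter$Aem, length(Q_grid))
    Fq <- Fq * exp(-(Aex + Aem) / 2)
  }
  quench_titration(temperature, Q_grid, Fq, Aex = Aex, Aem = Aem)
}

#' Generate a Van't Hoff-consistent Ka(T) series
#'
#' `Ka(T) = exp(-dH/(R T) + dS/R)` exactly (no noise), so
#' [vant_hoff_fit()] recovers `(dH, dS)` to machine precision.
#'
#' @param dH Standard enthalpy change, J/mol.
#' @param dS Standard entropy change, J/mol/K.
#' @param T_grid Temperatures, K; >= 2 distinct values.
#' @param R Gas constant, J/mol/K.
#' @return Data frame with columns `temperature_k`, `ka_l_per_mol`.
#' @export
#' @examples
#' gen_vant_hoff(-97170, -207.25, c(298, 304, 310))
gen_vant_hoff <- function(dH, dS, T_grid, R = 8.314) {
  if (length(unique(T_grid)) < 2L)
    stop("need at least 2 distinct temperatures")
  data.frame(temperature_k = T_grid,
             ka_l_per_mol = exp(-dH / (R * T_grid) + dS / R))
}

#' Generate a dose-response series
#'
#' Two-parameter logistic ground truth
#' `inhibition = 100 / (1 + (IC50/c)^hill)`: exactly 50% at `c = IC50`.
#'
#' @param ic50 True IC50, ug/mL (> 0).
#' @param hill Hill slope.
#' @param conc_grid Concentrations, ug/mL, strictly increasing.
#' @param noise_sd Gaussian noise sd in percent; default 0.
#' @param seed Optional integer seed.
#' @return A [dose_response_series()].
#' @export
gen_dose_response <- function(ic50, hill = 1, conc_grid, noise_sd = 0,
                              seed = NULL) {
  if (ic50 <= 0) stop("IC50 must be positive")
  y <- 100 / (1 + (ic50 / conc_grid)^hill)
  maybe_seed(seed)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  dose_response_series(conc_grid, y)
}

#' Generate synthetic spectra
#'
#' Dispatcher over the three spectral generators:
#' [gen_synchronous_series()], [gen_eem()] and [gen_ftir_spectrum()].
#'
#' @param kind `"synchronous"`, `"eem"` or `"ftir"`.
#' @param ... Passed to the specific generator.
#' @return See the specific generator.
#' @export
gen_spectra <- function(kind = c("synchronous", "eem", "ftir"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         synchronous = gen_synchronous_series(...),
         eem = gen_eem(...),
         ftir = gen_ftir_spectrum(...))
}

#' Generate a synchronous-fluorescence concentration ladder
#'
#' Gaussian emission peak whose center moves linearly with the
#' concentration index (`shift_per_step` nm per step; negative = blue
#' shift) and whose amplitude is scaled by the supplied quench factors.
#'
#' @param mode `"sync15"`, `"sync60"` or `"emission"`.
#' @param concentrations Ligand concentrations, ug/mL, first 0.
#' @param center0 Peak center of the reference spectrum, nm.
#' @param shift_per_step Center displacement per concentration step, nm.
#' @param sigma Gaussian width, nm.
#' @param F0 Reference peak amplitude.
#' @param quench_factors Per-concentration amplitude factors (first must
#'   be 1); default a geometric decay `0.85^step`.
#' @param wavelength Wavelength grid, nm.
#' @param noise_sd Gaussian noise sd on intensities; default 0.
#' @param seed Optional integer seed.
#' @return A [spectrum_series()].
#' @export
gen_synchronous_series <- function(mode = "sync60",
                                   concentrations = c(0, 5, 10, 15, 20, 25),
                                   center0 = 290, shift_per_step = 0,
                                   sigma = 12, F0 = 100,
                                   quench_factors = NULL,
                                   wavelength = seq(200, 400, by = 1),
                                   noise_sd = 0, seed = NULL) {
  nconc <- length(concentrations)
  if (is.null(quench_factors)) quench_factors <- 0.85^(seq_len(nconc) - 1)
  if (length(quench_factors) != nconc || quench_factors[1] != 1)
    stop("quench_factors must match concentrations and start at 1")
  maybe_seed(seed)
  mat <- vapply(seq_len(nconc), function(i) {
    mu <- center0 + shift_per_step * (i - 1)
    y <- F0 * quench_factors[i] * exp(-(wavelength - mu)^2 / (2 * sigma^2))
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    y
  }, numeric(length(wavelength)))
  spectrum_series(mode, wavelength, mat, concentrations)
}

#' Generate a synthetic excitation-emission matrix
#'
#' Sum of 2-D Gaussian peaks, optionally with a first-order Rayleigh
#' scatter ridge along `Em = Ex`.
#'
#' @param ex_grid,em_grid Wavelength grids, nm.
#' @param peaks Data frame with columns `ex`, `em`, `amplitude` and
#'   optionally `sigma_ex`, `sigma_em` (default 12 nm).
#' @param rayleigh_amplitude Height of the scatter ridge; default 0.
#' @param rayleigh_sigma Ridge width, nm; default 4.
#' @param noise_sd Gaussian noise sd; default 0.
#' @param seed Optional integer seed.
#' @return An [eem()].
#' @export
gen_eem <- function(ex_grid = seq(200, 600, by = 2),
                    em_grid = seq(200, 600, by = 2),
                    peaks = data.frame(ex = c(280, 236), em = c(352, 352),
                                       amplitude = c(300, 50)),
                    rayleigh_amplitude = 0, rayleigh_sigma = 4,
                    noise_sd = 0, seed = NULL) {
  if (is.null(peaks$sigma_ex)) peaks$sigma_ex <- 12
  if (is.null(peaks$sigma_em)) peaks$sigma_em <- 12
  M <- matrix(0, length(ex_grid), length(em_grid))
  for (r in seq_len(nrow(peaks))) {
    M <- M + peaks$amplitude[r] *
      outer(exp(-(ex_grid - peaks$ex[r])^2 / (2 * peaks$sigma_ex[r]^2)),
            exp(-(em_grid - peaks$em[r])^2 / (2 * peaks$sigma_em[r]^2)))
  }
  if (rayleigh_amplitude > 0) {
    M <- M + rayleigh_amplitude *
      outer(ex_grid, em_grid, function(e1, e2)
        exp(-(e2 - e1)^2 / (2 * rayleigh_sigma^2)))
  }
  maybe_seed(seed)
  if (noise_sd > 0) M <- M + matrix(stats::rnorm(length(M), 0, noise_sd),
                                    nrow(M), ncol(M))
  eem(ex_grid, em_grid, M)
}

# default sub-band centers, one per secondary-structure class
.default_amide_centers <- c(beta_sheet = 1626, beta_antiparallel = 1643,
                            alpha_helix = 1654.5, beta_turn = 1670.5,
                            random_coil = 1686.5)

#' Generate a synthetic FTIR spectrum with known class areas
#'
#' Sum of Gaussian sub-bands on the amide-I window, one per
#' secondary-structure class, with prescribed areas — the ground truth
#' for [deconvolve()] + [assign_structure()].
#'
#' @param class_areas Named numeric vector of areas (absorbance x cm^-1);
#'   names among `alpha_helix`, `beta_sheet`, `beta_turn`, `random_coil`,
#'   `beta_antiparallel`.  Zero-area classes are omitted.
#' @param centers Named centers, cm^-1; defaults near each class-range
#'   midpoint.  Must lie in `[1600, 1700]`.
#' @param sigma Gaussian sigma, cm^-1 (scalar or per class).  The default
#'   (5 cm^-1, FWHM ~ 11.8) keeps every component effectively supported
#'   inside the 1600-1700 window, matching the endpoint-anchored baseline
#'   of [extract_amide_I()].
#' @param wavenumber Grid, cm^-1; default 1600-1700 by 0.5.
#' @param baseline_slope,baseline_offset Optional straight-line baseline
#'   added to the signal (removed again by [extract_amide_I()]).
#' @param noise_sd Gaussian noise sd; default 0.
#' @param seed Optional integer seed.
#' @return An [ftir_spectrum()].
#' @export
#' @examples
#' sp <- gen_ftir_spectrum(c(alpha_helix = 24.58, beta_sheet = 27.34,
#'                           beta_turn = 23.64, random_coil = 14.10,
#'                           beta_antiparallel = 10.34))
gen_ftir_spectrum <- function(class_areas,
                              centers = .default_amide_centers,
                              sigma = 5,
                              wavenumber = seq(1600, 1700, by = 0.5),
                              baseline_slope = 0, baseline_offset = 0,
                              noise_sd = 0, seed = NULL) {
  stopifnot(!is.null(names(class_areas)))
  bad <- setdiff(names(class_areas), names(.default_amide_centers))
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  class_areas <- class_areas[class_areas > 0]
  ctr <- centers[names(class_areas)]
  if (any(ctr < 1600 | ctr > 1700))
    stop("peak centers must lie within 1600-1700 cm^-1")
  sg <- rep_len(sigma, length(class_areas))
  amps <- class_areas / (sg * sqrt(2 * pi))
  y <- gaussian_sum(wavenumber, ctr, sg, amps) +
    baseline_offset + baseline_slope * (wavenumber - wavenumber[1])
  maybe_seed(seed)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  ftir_spectrum(wavenumber, y)
}
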