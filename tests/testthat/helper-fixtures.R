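# shared fixtures built in code

# mixed-inhibition ground truth used across kinetics tests
mixed_truth <- list(km = 3.9047, vmax = 0.1826, ki = 8.7057, kis = 21.2847)

gen_mixed_fits <- function(inhibitor_grid = c(0, 2, 4, 6, 8, 10),
                           substrate_grid = c(2.5, 5, 7.5, 10)) {
  series <- gen_kinetics(mixed_truth$km, mixed_truth$vmax, "mixed",
                         ki = mixed_truth$ki, kis = mixed_truth$kis,
                         substrate_grid = substrate_grid,
                         inhibitor_grid = inhibitor_grid)
  lapply(series, fit_kinetics)
}

# published secondary-structure fraction vectors used as synthetic truths
amy_fractions <- c(alpha_helix = 24.58, beta_sheet = 27.34,
                   beta_turn = 23.64, random_coil = 14.10,
                   beta_antiparallel = 10.34)

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
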