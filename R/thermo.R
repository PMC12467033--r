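#' Van't Hoff analysis of temperature-dependent binding constants
#'
#' Ordinary least squares of `ln Ka` on `1/T`:
#' `ln Ka = -dH/(R T) + dS/R`, so the standard enthalpy change is
#' `dH = -R * slope` and the standard entropy change `dS = R * intercept`
#' (the intercept method — `dS` comes from the regression intercept, not
#' from `(dH - dG)/T`).  Per-temperature Gibbs free energies
#' `dG = -R T ln Ka` are attached, together with the `dH - T dS`
#' consistency variant and the binding-force classification from the sign
#' pattern of `dH` and `dS`.
#'
#' @param pairs Data frame with columns `temperature_k` and `ka_l_per_mol`
#'   (or `temperature`/`Ka`), >= 2 distinct temperatures, all `Ka > 0`.
#' @param R Gas constant, J/mol/K.
#' @return Object of class `"thermo_fit"`: `dH` (J/mol), `dS` (J/mol/K),
#'   `se_dH`, `se_dS`, `r_squared`, `dG_by_T` (named, J/mol, from
#'   `-RT ln Ka`), `dG_from_HS` (the `dH - T dS` variant), and `force`.
#' @export
#' @examples
#' tb <- quench_binding_constants("alpha_glucosidase", "THPP")
#' vant_hoff_fit(data.frame(temperature_k = tb$temperature_k,
#'                          ka_l_per_mol = tb$ka_1e5_l_per_mol * 1e5))
vant_hoff_fit <- function(pairs, R = 8.314) {
  nm <- names(pairs)
  Tk <- pairs[[if ("temperature_k" %in% nm) "temperature_k" else "temperature"]]
  Ka <- pairs[[if ("ka_l_per_mol" %in% nm) "ka_l_per_mol" else "Ka"]]
  if (is.null(Tk) || is.null(Ka))
    stop("pairs must have temperature and Ka columns")
  if (length(Tk) < 2L) stop("need >= 2 temperatures for a Van't Hoff fit")
  if (anyDuplicated(Tk)) stop("duplicate temperatures: rank-deficient fit")
  if (any(Ka <= 0)) stop("Ka must be positive (log domain)")
  o <- order(Tk); Tk <- Tk[o]; Ka <- Ka[o]
  fit <- stats::lm(y ~ x, data = data.frame(x = 1 / Tk, y = log(Ka)))
  co <- stats::coef(fit)
  dH <- -R * unname(co[2])
  dS <- R * unname(co[1])
  se <- if (length(Tk) > 2L)
    R * unname(suppressWarnings(summary(fit))$coefficients[, 2]) else c(NA_real_, NA_real_)
  r2 <- if (length(Tk) > 2L) suppressWarnings(summary(fit))$r.squared else 1
  dG <- -R * Tk * log(Ka)
  names(dG) <- as.character(Tk)
  dG_hs <- dH - Tk * dS
  names(dG_hs) <- as.character(Tk)
  structure(list(dH = dH, dS = dS, se_dS = se[1], se_dH = se[2],
                 r_squared = r2, temperature = Tk, Ka = Ka,
                 dG_by_T = dG, dG_from_HS = dG_hs, R = R,
                 force = classify_forces(dH, dS)),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("Van't Hoff analysis\n")
  cat(sprintf("  dH = %.2f kJ/mol, dS = %.2f J/mol/K  (R^2 = %.4f)\n",
              x$dH / 1000, x$dS, x$r_squared))
  for (i in seq_along(x$temperature))
    cat(sprintf("  dG(%g K) = %.2f kJ/mol\n",
                x$temperature[i], x$dG_by_T[i] / 1000))
  cat(sprintf("  dominant force: %s\n", x$force))
  invisible(x)
}

#' @export
coef.thermo_fit <- function(object, ...)
  c(dH = object$dH, dS = object$dS)

#' Gibbs free energy of binding
#'
#' `dG = -R T ln Ka` for a single temperature/binding-constant pair.
#'
#' @param T Temperature, K (> 0).
#' @param Ka Binding constant, L/mol (> 0).
#' @param R Gas constant, J/mol/K.
#' @return Gibbs free energy, J/mol.
#' @export
#' @examples
#' gibbs_free_energy(298, 15.49e5) / 1000  # ~ -35.3 kJ/mol
gibbs_free_energy <- function(T, Ka, R = 8.314) {
  if (any(T <= 0)) stop("temperature must be positive")
  if (any(Ka <= 0)) stop("Ka must be positive (log domain)")
  -R * T * log(Ka)
}

#' Classify the dominant intermolecular binding force
#'
#' Sign-pattern rules for the standard enthalpy and entropy of binding:
#' both positive — hydrophobic interaction; both negative — hydrogen
#' bonding and van der Waals forces; `dH < 0`, `dS > 0` — electrostatic
#' interaction.  The remaining pattern (`dH > 0`, `dS < 0`) has no rule
#' and is labeled `"out_of_ruleset"`.  Magnitudes below `epsilon` sit on a
#' sign boundary and are labeled `"boundary"` with a warning.
#'
#' @param dH Standard enthalpy change, J/mol.
#' @param dS Standard entropy change, J/mol/K.
#' @param epsilon Magnitude below which a sign is considered indeterminate.
#' @return One of `"hydrophobic"`, `"hbond_vdw"`, `"electrostatic"`,
#'   `"out_of_ruleset"`, `"boundary"`.
#' @export
#' @examples
#' classify_forces(-97170, -207.25)  # "hbond_vdw"
#' classify_forces(-15840, 49.67)    # "electrostatic"
classify_forces <- function(dH, dS, epsilon = 1e-9) {
  if (!is.finite(dH) || !is.finite(dS))
    stop("dH and dS must be finite")
  if (abs(dH) < epsilon || abs(dS) < epsilon) {
    warning("dH or dS magnitude below epsilon: sign-rule boundary")
    return("boundary")
  }
  if (dH > 0 && dS > 0) "hydrophobic"
  else if (dH < 0 && dS < 0) "hbond_vdw"
  else if (dH < 0 && dS > 0) "electrostatic"
  else "out_of_ruleset"
}
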