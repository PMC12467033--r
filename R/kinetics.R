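#' Kinetic series at one inhibitor concentration
#'
#' @param inhibitor_conc Inhibitor concentration, ug/mL (>= 0).
#' @param substrate Substrate concentrations, mmol/L (>= 3 distinct,
#'   positive).
#' @param velocity Reaction velocities, dOD/min (positive).
#' @return Object of class `"kinetic_series"`.
#' @export
kinetic_series <- function(inhibitor_conc, substrate, velocity) {
  substrate <- as.numeric(substrate); velocity <- as.numeric(velocity)
  if (length(substrate) != length(velocity))
    stop("substrate and velocity lengths differ")
  if (length(unique(substrate)) < 3L)
    stop("need at least 3 distinct substrate concentrations")
  if (any(substrate <= 0))
    stop(sprintf("non-positive substrate concentration at row %d",
                 which(substrate <= 0)[1]))
  if (any(velocity <= 0))
    stop(sprintf("non-positive velocity at row %d", which(velocity <= 0)[1]))
  structure(list(inhibitor_conc = as.numeric(inhibitor_conc),
                 substrate = substrate, velocity = velocity),
            class = "kinetic_series")
}

#' Fit apparent Michaelis-Menten parameters
#'
#' `"lineweaver_burk"` mode regresses `1/v` on `1/[S]` by ordinary least
#' squares and reads `Km = slope/intercept`, `Vmax = 1/intercept` — the
#' classical double-reciprocal analysis.  `"nonlinear"` mode fits
#' `v = Vmax [S] / (Km + [S])` directly by least squares.
#'
#' @param series A [kinetic_series()].
#' @param mode `"lineweaver_burk"` (default) or `"nonlinear"`.
#' @return Object of class `"kinetic_fit"`: `Km`, `Vmax`, standard errors,
#'   the Lineweaver-Burk slope (`Km/Vmax`) and intercept (`1/Vmax`), the
#'   fitting mode, `r_squared`, and the source inhibitor concentration.
#' @export
#' @examples
#' s <- gen_kinetics(km = 3.9, vmax = 0.18, type = "mixed",
#'                   ki = 8.7, kis = 21.3,
#'                   substrate_grid = c(2.5, 5, 7.5, 10),
#'                   inhibitor_grid = 0)[[1]]
#' fit_kinetics(s)
fit_kinetics <- function(series, mode = c("lineweaver_burk", "nonlinear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "kinetic_series"))
  S <- series$substrate; v <- series$velocity
  if (mode == "lineweaver_burk") {
    fit <- stats::lm(y ~ x, data = data.frame(x = 1 / S, y = 1 / v))
    co <- stats::coef(fit)
    b0 <- unname(co[1]); b1 <- unname(co[2])
    if (b0 <= 0)
      stop("ill-conditioned Lineweaver-Burk fit: non-positive 1/v intercept")
    if (b1 <= 0)
      stop("ill-conditioned Lineweaver-Burk fit: non-positive slope")
    Vmax <- 1 / b0
    Km <- b1 / b0
    sm <- suppressWarnings(summary(fit))$coefficients
    # delta-method standard errors for the reparameterization
    se_Vmax <- sm[1, 2] / b0^2
    se_Km <- Km * sqrt((sm[2, 2] / b1)^2 + (sm[1, 2] / b0)^2)
    r2 <- suppressWarnings(summary(fit))$r.squared
  } else {
    dat <- data.frame(S = S, v = v)
    start <- list(Vmax = max(v) * 1.2, Km = stats::median(S))
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat, start = start,
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e)
        stop(sprintf("nonlinear Michaelis-Menten fit failed: %s",
                     conditionMessage(e))))
    co <- stats::coef(fit)
    Vmax <- unname(co["Vmax"]); Km <- unname(co["Km"])
    se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                   error = function(e) c(Vmax = NA_real_, Km = NA_real_))
    se_Vmax <- unname(se["Vmax"]); se_Km <- unname(se["Km"])
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((v - mean(v))^2)
  }
  structure(list(Km = Km, Vmax = Vmax, se_Km = se_Km, se_Vmax = se_Vmax,
                 lb_slope = Km / Vmax, lb_intercept = 1 / Vmax,
                 mode = mode, r_squared = r2,
                 inhibitor_conc = series$inhibitor_conc),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Apparent Michaelis-Menten fit (%s) at [I] = %g ug/mL\n",
              x$mode, x$inhibitor_conc))
  cat(sprintf("  Km   = %.4f +/- %.4f mmol/L\n", x$Km, x$se_Km))
  cat(sprintf("  Vmax = %.4f +/- %.4f dOD/min   (R^2 = %.4f)\n",
              x$Vmax, x$se_Vmax, x$r_squared))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...)
  c(Km = object$Km, Vmax = object$Vmax)

# build a kinetic_fit directly from known apparent constants (e.g. a
# published table row); lb_slope/lb_intercept follow by identity
kinetic_fit_from_constants <- function(Km, Vmax, inhibitor_conc) {
  structure(list(Km = Km, Vmax = Vmax, se_Km = NA_real_, se_Vmax = NA_real_,
                 lb_slope = Km / Vmax, lb_intercept = 1 / Vmax,
                 mode = "tabulated", r_squared = NA_real_,
                 inhibitor_conc = inhibitor_conc),
            class = "kinetic_fit")
}

#' Assemble kinetic fits from a table of apparent constants
#'
#' Convenience for analyses that start from published apparent `Km`/`Vmax`
#' values rather than raw velocity data, e.g. the shipped
#' [kinetic_constants()] table.
#'
#' @param df Data frame with columns `inhibitor_ug_per_ml`,
#'   `km_app_mmol_per_l`, `vmax_app_dod_per_min`.
#' @return List of `"kinetic_fit"` objects ordered by inhibitor
#'   concentration.
#' @export
#' @examples
#' fits <- kinetic_fits_from_table(kinetic_constants("alpha_amylase", "TAPP"))
#' estimate_ki(fits)
kinetic_fits_from_table <- function(df) {
  need <- c("inhibitor_ug_per_ml", "km_app_mmol_per_l",
            "vmax_app_dod_per_min")
  if (!all(need %in% names(df)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$inhibitor_ug_per_ml), ]
  Map(kinetic_fit_from_constants, df$km_app_mmol_per_l,
      df$vmax_app_dod_per_min, df$inhibitor_ug_per_ml)
}

fits_table <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  d <- data.frame(
    I = vapply(fits, function(f) f$inhibitor_conc, numeric(1)),
    Km = vapply(fits, function(f) f$Km, numeric(1)),
    Vmax = vapply(fits, function(f) f$Vmax, numeric(1)),
    lb_slope = vapply(fits, function(f) f$lb_slope, numeric(1)),
    lb_intercept = vapply(fits, function(f) f$lb_intercept, numeric(1)))
  d[order(d$I), ]
}

#' Classify the inhibition type from apparent-constant trends
#'
#' Classification combines the Km/Vmax trends across inhibitor
#' concentrations with the geometry of the Lineweaver-Burk lines:
#' \itemize{
#'   \item Km constant (relative spread <= `tol`) and Vmax strictly
#'     decreasing: non-competitive;
#'   \item Km increasing and Vmax decreasing: mixed;
#'   \item Vmax constant and Km increasing: competitive;
#'   \item Km and Vmax decreasing proportionally (constant Km/Vmax):
#'     uncompetitive.
#' }
#' The centroid of all pairwise Lineweaver-Burk line intersections is also
#' reported; an intersection in the second quadrant corroborates mixed
#' inhibition, one on the negative x-axis non-competitive inhibition.
#' When trend and geometry evidence disagree the result is labeled
#' `"ambiguous"` and carries both signals.
#'
#' @param fits List of [fit_kinetics()] results (or
#'   [kinetic_fits_from_table()]) at >= 3 inhibitor concentrations
#'   including `[I] = 0`.
#' @param tol Relative Km-constancy (and Vmax-constancy) tolerance;
#'   default 0.05.
#' @return Object of class `"inhibition_class"` with elements `type`,
#'   `evidence` (trend summary), `intersection` (centroid x, y, quadrant
#'   label, dispersion), and `geometry_type`.
#' @export
#' @examples
#' fits <- kinetic_fits_from_table(
#'   kinetic_constants("alpha_amylase", "Ni-TCPP"))
#' classify_inhibition(fits)$type
classify_inhibition <- function(fits, tol = 0.05) {
  d <- fits_table(fits)
  if (nrow(d) < 3L) stop("need fits at >= 3 inhibitor concentrations")
  if (min(d$I) != 0) stop("fits must include the uninhibited ([I] = 0) series")

  km_spread <- (max(d$Km) - min(d$Km)) / d$Km[1]
  vmax_spread <- (max(d$Vmax) - min(d$Vmax)) / d$Vmax[1]
  km_const <- km_spread <= tol
  vmax_const <- vmax_spread <= tol
  km_up <- all(diff(d$Km) > 0)
  km_down <- all(diff(d$Km) < 0)
  vmax_down <- all(diff(d$Vmax) < 0)
  ratio_spread <- (max(d$lb_slope) - min(d$lb_slope)) / d$lb_slope[1]

  trend <-
    if (km_const && vmax_down) "noncompetitive"
    else if (!km_const && km_down && vmax_down && ratio_spread <= tol)
      "uncompetitive"
    else if (km_up && vmax_const) "competitive"
    else if (km_up && vmax_down) "mixed"
    else "indeterminate"

  # pairwise intersections of the LB lines y = lb_intercept + lb_slope * x
  n <- nrow(d)
  xs <- ys <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ds <- d$lb_slope[i] - d$lb_slope[j]
    if (abs(ds) < 1e-12 * max(d$lb_slope)) next  # near-parallel pair
    x <- (d$lb_intercept[j] - d$lb_intercept[i]) / ds
    xs <- c(xs, x); ys <- c(ys, d$lb_intercept[i] + d$lb_slope[i] * x)
  }
  if (length(xs)) {
    cx <- mean(xs); cy <- mean(ys)
    disp <- if (length(xs) > 1)
      sqrt(stats::var(xs) + stats::var(ys)) else 0
    axis_tol <- tol * max(d$lb_intercept)   # y scale: 1/Vmax
    x_tol <- tol * mean(1 / d$Km)           # x scale: -1/Km
    quadrant <-
      if (abs(cx) <= x_tol) "y_axis"
      else if (cx < 0 && cy > axis_tol) "second_quadrant"
      else if (cx < 0 && abs(cy) <= axis_tol) "negative_x_axis"
      else if (cx > 0 && cy > 0) "first_quadrant"
      else "other"
    geometry_type <- switch(quadrant,
                            second_quadrant = "mixed",
                            negative_x_axis = "noncompetitive",
                            NA_character_)
    intersection <- list(x = cx, y = cy, quadrant = quadrant,
                         dispersion = disp)
  } else {
    geometry_type <- NA_character_
    intersection <- list(x = NA_real_, y = NA_real_, quadrant = "parallel",
                         dispersion = NA_real_)
  }

  type <- trend
  if (!is.na(geometry_type) && trend %in% c("mixed", "noncompetitive") &&
      geometry_type != trend)
    type <- "ambiguous"
  if (trend == "indeterminate" && !is.na(geometry_type))
    type <- geometry_type

  structure(list(type = type,
                 evidence = list(trend = trend, km_spread = km_spread,
                                 vmax_spread = vmax_spread,
                                 km_increasing = km_up,
                                 vmax_decreasing = vmax_down,
                                 tol = tol),
                 geometry_type = geometry_type,
                 intersection = intersection),
            class = "inhibition_class")
}

#' @export
print.inhibition_class <- function(x, ...) {
  cat(sprintf("Inhibition type: %s\n", x$type))
  cat(sprintf("  trend: %s (Km spread %.1f%%, Vmax spread %.1f%%)\n",
              x$evidence$trend, 100 * x$evidence$km_spread,
              100 * x$evidence$vmax_spread))
  cat(sprintf("  LB intersection centroid (%.4g, %.4g), %s\n",
              x$intersection$x, x$intersection$y, x$intersection$quadrant))
  invisible(x)
}

secondary_regression <- function(x, y) {
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  co <- stats::coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       se = unname(suppressWarnings(summary(fit))$coefficients[, 2]))
}

#' Estimate the free-enzyme inhibition constant Ki
#'
#' Secondary-plot analysis: the Lineweaver-Burk slope (`Km/Vmax`, apparent)
#' is regressed on inhibitor concentration; the slope of that regression is
#' `Km/(Vmax Ki)` and its intercept `Km/Vmax`, so
#' `Ki = intercept / slope`.  Both values come from the secondary
#' regression itself (not the measured `[I] = 0` point), which is what
#' reproduces published constants from rounded tables.
#'
#' @param fits List of `"kinetic_fit"` objects at >= 3 inhibitor
#'   concentrations.
#' @return Object of class `"ki_fit"`: `Ki` (ug/mL), the secondary
#'   regression's `intercept`, `slope`, `r_squared` and standard errors.
#' @export
#' @examples
#' fits <- kinetic_fits_from_table(kinetic_constants("alpha_amylase", "TAPP"))
#' estimate_ki(fits)$Ki  # ~ 8.7 ug/mL
estimate_ki <- function(fits) {
  d <- fits_table(fits)
  if (nrow(d) < 3L) stop("need >= 3 inhibitor concentrations")
  reg <- secondary_regression(d$I, d$lb_slope)
  if (reg$slope <= 0)
    stop("no inhibition signal: secondary slope (LB slope vs [I]) is not positive")
  structure(list(Ki = reg$intercept / reg$slope, intercept = reg$intercept,
                 slope = reg$slope, r_squared = reg$r_squared, se = reg$se),
            class = "ki_fit")
}

#' Estimate the enzyme-substrate-complex inhibition constant Kis
#'
#' Secondary-plot analysis of the Lineweaver-Burk y-intercept: `1/Vmax`
#' (apparent) is regressed on inhibitor concentration; the intercept is
#' `1/Vmax` and the slope `1/(Vmax Kis)`, so `Kis = intercept / slope`.
#' Only defined for mixed inhibition — for a non-competitive or
#' uncompetitive classification call it is not applicable.
#'
#' @inheritParams estimate_ki
#' @param type Optional inhibition-type label (e.g. from
#'   [classify_inhibition()]); `"noncompetitive"` or `"uncompetitive"`
#'   raise a not-applicable error.
#' @return Object of class `"ki_fit"` with element `Kis`.
#' @export
#' @examples
#' fits <- kinetic_fits_from_table(kinetic_constants("alpha_amylase", "TAPP"))
#' estimate_kis(fits)$Kis  # ~ 21.3 ug/mL
estimate_kis <- function(fits, type = NULL) {
  if (!is.null(type) && type %in% c("noncompetitive", "uncompetitive"))
    stop(sprintf("Kis is not applicable for %s inhibition", type))
  d <- fits_table(fits)
  if (nrow(d) < 3L) stop("need >= 3 inhibitor concentrations")
  reg <- secondary_regression(d$I, d$lb_intercept)
  if (reg$slope <= 0)
    stop("no inhibition signal: secondary slope (1/Vmax vs [I]) is not positive")
  structure(list(Kis = reg$intercept / reg$slope, intercept = reg$intercept,
                 slope = reg$slope, r_squared = reg$r_squared, se = reg$se),
            class = "ki_fit")
}

#' @export
print.ki_fit <- function(x, ...) {
  k <- if ("Ki" %in% names(x)) c("Ki", x[["Ki"]]) else c("Kis", x[["Kis"]])
  cat(sprintf("%s = %.4f ug/mL  (secondary plot R^2 = %.4f)\n",
              k[1], as.numeric(k[2]), x$r_squared))
  invisible(x)
}
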