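#' Enzyme inhibition rate from assay absorbances
#'
#' Inhibition (%) from the four-absorbance plate layout:
#' `A1` sample group, `A2` sample control (enzyme replaced by buffer),
#' `A3` blank control, `A4` reagent blank.  The rate is
#' `(1 - (A1 - A2)/(A3 - A4)) * 100` and may legitimately fall below 0 or
#' exceed 100 for activating or fully-suppressed wells.
#'
#' @param A1,A2,A3,A4 Absorbance readings (finite numerics, vectorized).
#' @return Inhibition rate in percent.
#' @export
#' @examples
#' inhibition_rate(0.5, 0.1, 0.9, 0.1)  # 50
inhibition_rate <- function(A1, A2, A3, A4) {
  stopifnot_finite(c(A1, A2, A3, A4), "absorbances")
  if (any(A3 - A4 == 0))
    stop("blank pair degenerate: A3 - A4 = 0 (division by zero)")
  (1 - (A1 - A2) / (A3 - A4)) * 100
}

#' Cell viability from MTT absorbances
#'
#' Survival (%) of treated cells: `As` sample well, `Ac` blank control well
#' (cells, no drug), `Ab` solvent control well (no cells, no drug);
#' viability = `(As - Ab)/(Ac - Ab) * 100`.
#'
#' @param As,Ac,Ab Absorbance readings (finite, vectorized).
#' @return Viability in percent.
#' @export
#' @examples
#' cell_viability(0.6, 1.1, 0.1)  # 50
cell_viability <- function(As, Ac, Ab) {
  stopifnot_finite(c(As, Ac, Ab), "absorbances")
  if (any(Ac - Ab == 0))
    stop("control pair degenerate: Ac - Ab = 0 (division by zero)")
  (As - Ab) / (Ac - Ab) * 100
}

#' Dose-response series
#'
#' @param concentration Inhibitor concentrations, ug/mL, strictly
#'   increasing and non-negative.
#' @param inhibition Inhibition rates, percent.
#' @param replicate_sd Optional per-point replicate standard deviation.
#' @param compound,enzyme Optional labels.
#' @return Object of class `"dose_response_series"`.
#' @export
dose_response_series <- function(concentration, inhibition,
                                 replicate_sd = NULL,
                                 compound = NA_character_,
                                 enzyme = NA_character_) {
  concentration <- as.numeric(concentration)
  inhibition <- as.numeric(inhibition)
  if (length(concentration) != length(inhibition))
    stop("concentration and inhibition lengths differ")
  if (any(concentration < 0))
    stop(sprintf("negative concentration at row %d",
                 which(concentration < 0)[1]))
  if (any(diff(concentration) <= 0))
    stop(sprintf("concentrations not strictly increasing at row %d",
                 which(diff(concentration) <= 0)[1] + 1L))
  stopifnot_finite(inhibition, "inhibition")
  structure(list(concentration = concentration, inhibition = inhibition,
                 replicate_sd = replicate_sd, compound = compound,
                 enzyme = enzyme),
            class = "dose_response_series")
}

#' Estimate IC50 from a dose-response series
#'
#' Two estimators are available.  `"linear_interpolation"` takes the
#' concentration at which the inhibition-vs-concentration polyline crosses
#' 50%, using the two bracketing points (assumption-free; the default).
#' `"four_parameter_logistic"` fits
#' `y = bottom + (top - bottom) / (1 + (IC50/c)^hill)` by nonlinear least
#' squares and reports the fitted midpoint.
#'
#' @param series A [dose_response_series()].
#' @param method `"linear_interpolation"` or `"four_parameter_logistic"`.
#' @return Object of class `"ic50_fit"` with elements `ic50` (ug/mL),
#'   `method`, `fit_quality` (R^2 of the local line, or of the 4PL fit),
#'   and for the 4PL the full coefficient set and standard errors.
#' @export
#' @examples
#' s <- gen_dose_response(ic50 = 10, hill = 1,
#'                        conc_grid = c(2, 5, 10, 20, 50))
#' estimate_ic50(s)$ic50
estimate_ic50 <- function(series,
                          method = c("linear_interpolation",
                                     "four_parameter_logistic")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dose_response_series"))
  x <- series$concentration
  y <- series$inhibition
  if (length(x) < 4L) stop("need at least 4 dose-response points")

  if (method == "linear_interpolation") {
    hit <- which(y == 50)
    if (length(hit)) {
      return(structure(list(ic50 = x[hit[1]], method = method,
                            fit_quality = 1, ci = NULL),
                       class = "ic50_fit"))
    }
    cross <- which(diff(sign(y - 50)) != 0)
    if (!length(cross))
      stop("50% inhibition is not bracketed by the data; cannot interpolate")
    i <- cross[1]
    ic50 <- x[i] + (50 - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
    structure(list(ic50 = ic50, method = method, fit_quality = 1, ci = NULL),
              class = "ic50_fit")
  } else {
    dat <- data.frame(x = x, y = y)
    start <- list(bottom = max(min(y), 0), top = min(max(y), 100),
                  ic50 = stats::approx(y, x, xout = 50, ties = "ordered",
                                       rule = 2)$y,
                  hill = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (ic50 / x)^hill),
        data = dat, start = start,
        lower = c(-50, 0, min(x[x > 0]) / 100, 0.1),
        upper = c(100, 200, max(x) * 100, 10),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e)
        stop(sprintf("4PL fit failed to converge: %s", conditionMessage(e))))
    co <- stats::coef(fit)
    res <- stats::resid(fit)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 4))
    structure(list(ic50 = unname(co["ic50"]), method = method,
                   fit_quality = r2, coefficients = as.list(co),
                   se = as.list(se), ci = NULL),
              class = "ic50_fit")
  }
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g ug/mL  (%s", x$ic50, x$method))
  if (!is.null(x$fit_quality)) cat(sprintf(", R^2 = %.4f", x$fit_quality))
  cat(")\n")
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) c(ic50 = object$ic50)

#' Reversibility assay series
#'
#' Velocity vs enzyme activity at one inhibitor concentration.  A reversible
#' inhibitor gives straight lines through the origin whose slope falls as
#' inhibitor concentration rises.
#'
#' @param inhibitor_conc Inhibitor concentration, ug/mL.
#' @param enzyme_activity Enzyme activities, U/L (>= 3 points, positive).
#' @param velocity Reaction velocities, dOD/min.
#' @return Object of class `"reversibility_series"`.
#' @export
reversibility_series <- function(inhibitor_conc, enzyme_activity, velocity) {
  enzyme_activity <- as.numeric(enzyme_activity)
  velocity <- as.numeric(velocity)
  if (length(enzyme_activity) < 3L)
    stop("need at least 3 points per reversibility line")
  if (any(enzyme_activity <= 0)) stop("enzyme activities must be positive")
  stopifnot_finite(velocity, "velocity")
  structure(list(inhibitor_conc = as.numeric(inhibitor_conc),
                 enzyme_activity = enzyme_activity, velocity = velocity),
            class = "reversibility_series")
}

#' Reversibility verdict from velocity-vs-enzyme lines
#'
#' Fits `v = a + b * [E]` for each inhibitor concentration.  The inhibition
#' is called reversible when every intercept is within
#' `origin_tolerance * max(v)` of zero and the slopes strictly decrease
#' with increasing inhibitor concentration; otherwise the failing
#' condition(s) are named.
#'
#' @param lines List of [reversibility_series()] (>= 2 concentrations).
#' @param origin_tolerance Intercept tolerance as a fraction of the maximum
#'   velocity; default 0.05.
#' @return Object of class `"reversibility_verdict"` with elements
#'   `reversible` (logical), `flags` (character), and a per-line table of
#'   intercepts and slopes.
#' @export
reversibility_verdict <- function(lines, origin_tolerance = 0.05) {
  stopifnot(is.list(lines), length(lines) >= 2L)
  conc <- vapply(lines, function(l) l$inhibitor_conc, numeric(1))
  o <- order(conc)
  lines <- lines[o]; conc <- conc[o]
  fits <- lapply(lines, function(l) {
    if (length(unique(l$enzyme_activity)) < 2L)
      stop("degenerate line: all enzyme activities equal (rank-deficient)")
    stats::lm(velocity ~ enzyme_activity,
              data = data.frame(enzyme_activity = l$enzyme_activity,
                                velocity = l$velocity))
  })
  a <- vapply(fits, function(f) unname(stats::coef(f)[1]), numeric(1))
  b <- vapply(fits, function(f) unname(stats::coef(f)[2]), numeric(1))
  vmax <- max(vapply(lines, function(l) max(l$velocity), numeric(1)))
  flags <- character(0)
  if (any(abs(a) > origin_tolerance * vmax))
    flags <- c(flags, "not_through_origin")
  if (any(diff(b) >= 0))
    flags <- c(flags, "slopes_not_decreasing")
  structure(list(reversible = length(flags) == 0L, flags = flags,
                 table = data.frame(inhibitor_ug_per_ml = conc,
                                    intercept = a, slope = b),
                 origin_tolerance = origin_tolerance),
            class = "reversibility_verdict")
}

#' @export
print.reversibility_verdict <- function(x, ...) {
  cat(sprintf("Reversibility: %s\n",
              if (x$reversible) "reversible"
              else paste("failed:", paste(x$flags, collapse = ", "))))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Stability profile across conditions
#'
#' Applies [inhibition_rate()] over a grid of conditions (e.g. temperature
#' or pH) and summarizes the flatness of the profile.
#'
#' @param grid Named list; each element is a numeric vector or list with
#'   absorbances `A1`, `A2`, `A3`, `A4`.  Names label the conditions.
#' @return Object of class `"stability_profile"`: per-condition inhibition
#'   rates, the range (max - min), and the condition of maximum inhibition.
#' @export
#' @examples
#' g <- list(`30C` = c(A1 = .4, A2 = .1, A3 = .9, A4 = .1),
#'           `40C` = c(A1 = .5, A2 = .1, A3 = .9, A4 = .1))
#' stability_profile(g)
stability_profile <- function(grid) {
  stopifnot(is.list(grid), length(grid) >= 2L, !is.null(names(grid)))
  rates <- vapply(grid, function(a) {
    a <- as.list(a)
    inhibition_rate(a$A1, a$A2, a$A3, a$A4)
  }, numeric(1))
  structure(list(rates = rates, range = max(rates) - min(rates),
                 max_condition = names(rates)[which.max(rates)]),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("Stability profile (inhibition %, by condition):\n")
  print(round(x$rates, 2))
  cat(sprintf("range = %.2f; maximum at '%s'\n", x$range, x$max_condition))
  invisible(x)
}
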