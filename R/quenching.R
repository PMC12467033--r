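#' Fluorescence quench titration
#'
#' Peak emission intensities of a protein titrated with increasing quencher
#' (ligand) concentration at one temperature.  The first point must be the
#' quencher-free reference; its (corrected) intensity defines `F0`.
#' Optional per-point absorbances at the excitation and emission
#' wavelengths enable inner-filter correction.
#'
#' @param temperature Temperature, K.
#' @param Q Quencher concentrations, mol/L: non-negative, strictly
#'   increasing, first element 0.
#' @param Fobs Observed intensities (positive).
#' @param Aex,Aem Optional absorbances at excitation/emission wavelengths
#'   (non-negative, same length as `Q`).
#' @return Object of class `"quench_titration"`.
#' @export
quench_titration <- function(temperature, Q, Fobs, Aex = NULL, Aem = NULL) {
  Q <- as.numeric(Q); Fobs <- as.numeric(Fobs)
  if (length(Q) != length(Fobs)) stop("Q and Fobs lengths differ")
  if (Q[1] != 0) stop("first titration point must be quencher-free (Q = 0)")
  if (any(Q < 0)) stop(sprintf("negative concentration at row %d",
                               which(Q < 0)[1]))
  if (any(diff(Q) <= 0))
    stop(sprintf("quencher concentrations not strictly increasing at row %d",
                 which(diff(Q) <= 0)[1] + 1L))
  if (any(Fobs <= 0)) stop(sprintf("non-positive intensity at row %d",
                                   which(Fobs <= 0)[1]))
  for (a in list(Aex = Aex, Aem = Aem)) {
    if (!is.null(a) && (length(a) != length(Q) || any(a < 0)))
      stop("absorbances must be non-negative and match the titration length")
  }
  structure(list(temperature = as.numeric(temperature), Q = Q, Fobs = Fobs,
                 Aex = Aex, Aem = Aem, F0 = Fobs[1]),
            class = "quench_titration")
}

#' Inner-filter correction of titration intensities
#'
#' Re-absorption of excitation and emission light by the sample attenuates
#' the measured fluorescence.  The multiplicative correction
#' `Fcor = Fobs * exp((Aex + Aem)/2)` restores the true intensity.  All
#' points, including the quencher-free reference, are corrected; the
#' absorbances are zeroed afterwards so the operation is idempotent.
#' Titrations without absorbances pass through unchanged with a warning.
#'
#' @param t A [quench_titration()].
#' @return The corrected `"quench_titration"`.
#' @export
#' @examples
#' t <- quench_titration(298, c(0, 1e-6), c(100, 90),
#'                       Aex = c(0.1, 0.1), Aem = c(0.3, 0.3))
#' inner_filter_correct(t)$Fobs  # x exp(0.2)
inner_filter_correct <- function(t) {
  stopifnot(inherits(t, "quench_titration"))
  if (is.null(t$Aex) || is.null(t$Aem)) {
    warning("no excitation/emission absorbances: intensities left uncorrected")
    return(t)
  }
  t$Fobs <- t$Fobs * exp((t$Aex + t$Aem) / 2)
  t$F0 <- t$Fobs[1]
  t$Aex <- rep(0, length(t$Q))
  t$Aem <- rep(0, length(t$Q))
  t
}

#' Stern-Volmer quenching analysis
#'
#' Fits both the linear Stern-Volmer law `F0/F = 1 + Ksv [Q]` and its
#' exponential variant `F0/F = exp(Ksv [Q])` (used when the plot curves
#' upward, signalling combined static and dynamic quenching) by least
#' squares, selects the better model by residual sum of squares with a 5%
#' minimum-improvement guard for the exponential, and derives the
#' bimolecular quenching rate constant `Kq = Ksv / tau0`.
#'
#' @param t A [quench_titration()] (inner-filter corrected if absorbances
#'   were recorded); >= 4 points.
#' @param tau0 Fluorophore lifetime, s; default `1e-8`.
#' @param curvature_guard Minimum relative RSS improvement required to
#'   prefer the exponential model; default 0.05.
#' @return Object of class `"sv_fit"`: `Ksv` (L/mol), `Kq` (L/mol/s),
#'   `model` (`"linear"` or `"exponential"`), `curvature_score` (relative
#'   RSS improvement of the exponential form), `r_squared`, and the
#'   titration temperature.
#' @export
#' @examples
#' Q <- c(0, 2, 4, 6, 8) * 1e-6
#' t <- quench_titration(298, Q, 100 / (1 + 2e4 * Q))
#' stern_volmer_fit(t)$Ksv
stern_volmer_fit <- function(t, tau0 = 1e-8, curvature_guard = 0.05) {
  stopifnot(inherits(t, "quench_titration"))
  if (length(t$Q) < 4L) stop("need at least 4 titration points")
  ratio <- t$F0 / t$Fobs
  if (any(ratio < 1 - 1e-12))
    stop(sprintf("F0/F < 1 at row %d: enhancement, not quenching",
                 which(ratio < 1 - 1e-12)[1]))
  lin <- stats::lm(y ~ x, data = data.frame(x = t$Q, y = ratio))
  ksv_lin <- unname(stats::coef(lin)[2])
  rss_lin <- sum(stats::resid(lin)^2)
  ex <- stats::lm(y ~ x, data = data.frame(x = t$Q, y = log(ratio)))
  ksv_exp <- unname(stats::coef(ex)[2])
  rss_exp <- sum((exp(stats::fitted(ex)) - ratio)^2)
  # floor the linear RSS at numerical noise so exactly-linear data score 0
  rss_floor <- 1e-20 * sum(ratio^2)
  curvature <- if (rss_lin > rss_floor) (rss_lin - rss_exp) / rss_lin else 0
  use_exp <- rss_lin > rss_floor && curvature > curvature_guard
  ksv <- if (use_exp) ksv_exp else ksv_lin
  ksv <- max(ksv, 0)  # flat titrations regress to ~0, never negative
  tss <- sum((ratio - mean(ratio))^2)
  r2 <- if (tss > 0) 1 - (if (use_exp) rss_exp else rss_lin) / tss else 1
  structure(list(Ksv = ksv, Kq = ksv / tau0,
                 model = if (use_exp) "exponential" else "linear",
                 curvature_score = curvature, r_squared = r2,
                 tau0 = tau0, temperature = t$temperature),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf(
    "Stern-Volmer fit (%s) at %g K: Ksv = %.4g L/mol, Kq = %.4g L/mol/s\n",
    x$model, x$temperature, x$Ksv, x$Kq))
  cat(sprintf("  curvature score %.3f, R^2 = %.4f\n",
              x$curvature_score, x$r_squared))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) c(Ksv = object$Ksv, Kq = object$Kq)

#' Classify the quenching mechanism across temperatures
#'
#' Static (complex-forming) quenching shows `Ksv` decreasing with
#' temperature and apparent `Kq` far above the diffusion-limited ceiling
#' (`2e10` L/mol/s); dynamic (collisional) quenching shows the opposite
#' temperature trend or a diffusion-compatible `Kq`.  An upward-curved
#' (exponential) Stern-Volmer plot with the static temperature signature
#' marks combined quenching in which the static component dominates.
#'
#' @param results List of [stern_volmer_fit()] results at >= 2 distinct
#'   temperatures, or a data frame with columns `temperature`, `Ksv`, and
#'   optionally `model` (default `"linear"`).
#' @param threshold Kq threshold, L/mol/s; default `2e10`.
#' @param tau0 Lifetime used to derive Kq when `results` is a data frame.
#' @return Object of class `"quench_mechanism"` with elements `mechanism`
#'   (`"static"`, `"mixed_static_dominant"`, `"dynamic"` or
#'   `"indeterminate"`) and `evidence`.
#' @export
#' @examples
#' df <- data.frame(temperature = c(298, 304, 310),
#'                  Ksv = c(4.07e4, 3.37e4, 3.07e4))
#' classify_mechanism(df)$mechanism  # "static"
classify_mechanism <- function(results, threshold = 2e10, tau0 = 1e-8) {
  if (is.data.frame(results)) {
    stopifnot(all(c("temperature", "Ksv") %in% names(results)))
    if (is.null(results$model)) results$model <- "linear"
    Tk <- results$temperature; ksv <- results$Ksv
    model <- results$model; kq <- ksv / tau0
  } else {
    stopifnot(all(vapply(results, inherits, logical(1), "sv_fit")))
    Tk <- vapply(results, function(r) r$temperature, numeric(1))
    ksv <- vapply(results, function(r) r$Ksv, numeric(1))
    kq <- vapply(results, function(r) r$Kq, numeric(1))
    model <- vapply(results, function(r) r$model, character(1))
  }
  if (length(Tk) < 2L) stop("need results at >= 2 temperatures")
  if (anyDuplicated(Tk)) stop("temperatures must be distinct")
  o <- order(Tk)
  Tk <- Tk[o]; ksv <- ksv[o]; kq <- kq[o]; model <- model[o]
  ksv_decreasing <- all(diff(ksv) < 0)
  ksv_increasing <- all(diff(ksv) > 0)
  above <- all(kq > threshold)
  any_exp <- any(model == "exponential")
  mechanism <-
    if (ksv_decreasing && above && !any_exp) "static"
    else if (ksv_decreasing && above && any_exp) "mixed_static_dominant"
    else if (ksv_increasing || !above) "dynamic"
    else "indeterminate"
  structure(list(mechanism = mechanism,
                 evidence = list(temperature = Tk, Ksv = ksv, Kq = kq,
                                 model = model, threshold = threshold,
                                 ksv_decreasing = ksv_decreasing,
                                 all_kq_above_threshold = above)),
            class = "quench_mechanism")
}

#' @export
print.quench_mechanism <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s\n", x$mechanism))
  ev <- x$evidence
  cat(sprintf("  Ksv(%s K) = %s L/mol; all Kq > %.2g L/mol/s: %s\n",
              paste(ev$temperature, collapse = "/"),
              paste(signif(ev$Ksv, 4), collapse = "/"),
              ev$threshold, ev$all_kq_above_threshold))
  invisible(x)
}

#' Binding constant and stoichiometry from the double-log plot
#'
#' For static quenching, `log10((F0 - F)/F)` is linear in `log10 [Q]` with
#' slope equal to the number of binding sites `n` and intercept
#' `log10 Ka`.  Ordinary least squares over the `Q > 0` points.
#'
#' @param t A [quench_titration()] with strict quenching (`F < F0`) at all
#'   `Q > 0`.
#' @return Object of class `"binding_fit"`: `Ka` (L/mol), `n`,
#'   `r_squared`, `temperature`.
#' @export
#' @examples
#' Q <- c(0, 1, 2, 4, 8) * 1e-6
#' t <- quench_titration(298, Q, 100 / (1 + 1e5 * Q))
#' double_log_fit(t)  # Ka = 1e5, n = 1
double_log_fit <- function(t) {
  stopifnot(inherits(t, "quench_titration"))
  keep <- t$Q > 0
  Fq <- t$Fobs[keep]; Q <- t$Q[keep]
  bad <- which(Fq >= t$F0)
  if (length(bad))
    stop(sprintf("F >= F0 at Q > 0 (rows %s): double-log model undefined",
                 paste(which(keep)[bad], collapse = ", ")))
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(Q),
                                            y = log10((t$F0 - Fq) / Fq)))
  co <- stats::coef(fit)
  structure(list(Ka = 10^unname(co[1]), n = unname(co[2]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 temperature = t$temperature),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %g K: Ka = %.4g L/mol, n = %.3f (R^2 = %.4f)\n",
              x$temperature, x$Ka, x$n, x$r_squared))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) c(Ka = object$Ka, n = object$n)
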