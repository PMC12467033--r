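#' Spectrum series over a ligand-concentration ladder
#'
#' A set of 1-D spectra (synchronous fluorescence at a fixed
#' excitation-emission offset, or plain emission) recorded on a common
#' wavelength grid at increasing ligand concentrations, the first being
#' the protein-alone reference.
#'
#' @param mode `"sync15"` (delta-lambda = 15 nm, tyrosine channel),
#'   `"sync60"` (delta-lambda = 60 nm, tryptophan channel) or
#'   `"emission"`.
#' @param wavelength Common wavelength grid, nm, strictly increasing.
#' @param intensities Matrix (rows = wavelengths, columns = concentrations)
#'   or list of intensity vectors.
#' @param concentrations Ligand concentrations, ug/mL; first must be 0.
#' @return Object of class `"spectrum_series"`.
#' @export
spectrum_series <- function(mode = c("sync15", "sync60", "emission"),
                            wavelength, intensities, concentrations) {
  mode <- match.arg(mode)
  wavelength <- as.numeric(wavelength)
  if (any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (is.list(intensities)) intensities <- do.call(cbind, intensities)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavelength))
    stop("intensity rows must match the wavelength grid")
  if (ncol(intensities) != length(concentrations))
    stop("one intensity column per concentration required")
  if (concentrations[1] != 0)
    stop("first spectrum must be the ligand-free (0 ug/mL) reference")
  stopifnot_finite(intensities, "intensities")
  structure(list(mode = mode, wavelength = wavelength,
                 intensities = intensities,
                 concentrations = as.numeric(concentrations)),
            class = "spectrum_series")
}

# apex of each spectrum: parabolic interpolation around the discrete
# maximum gives sub-grid peak positions; ties break to shorter wavelength
spectrum_apex <- function(wavelength, y) {
  if (max(y) == min(y)) stop("flat spectrum: no peak")
  i <- which.max(y)          # which.max takes the first (shortest) maximum
  if (i == 1L || i == length(y))
    return(list(position = wavelength[i], intensity = y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(list(position = wavelength[i], intensity = y[i]))
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  h <- wavelength[i + 1] - wavelength[i]
  list(position = wavelength[i] + delta * h,
       intensity = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
}

#' Relative synchronous fluorescence quenching
#'
#' `RSFQ_i = 1 - F_i / F_0` where `F` is each spectrum's peak intensity
#' and `F_0` that of the ligand-free reference.  By construction the
#' reference value is 0; for quenched series (`F <= F0`) RSFQ lies in
#' `[0, 1]`.
#'
#' @param series A [spectrum_series()].
#' @return Data frame with columns `concentration` and `rsfq`.
#' @export
rsfq <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  peaks <- apply(series$intensities, 2, function(y)
    spectrum_apex(series$wavelength, y)$intensity)
  if (peaks[1] == 0) stop("degenerate reference: F0 = 0")
  data.frame(concentration = series$concentrations,
             rsfq = 1 - peaks / peaks[1])
}

#' Peak shift across a concentration ladder
#'
#' Compares the (parabolically interpolated) peak position of the
#' highest-concentration spectrum against the ligand-free reference.
#' Displacements within `threshold_nm` are reported as `"none"`; shorter
#' wavelengths are a `"blue"` shift, longer a `"red"` shift.
#'
#' @param series A [spectrum_series()].
#' @param threshold_nm Shift threshold, nm; default one grid step.
#' @return Object of class `"peak_shift"`: `direction`, `magnitude_nm`,
#'   and the two peak positions.
#' @export
peak_shift <- function(series, threshold_nm = NULL) {
  stopifnot(inherits(series, "spectrum_series"))
  if (is.null(threshold_nm))
    threshold_nm <- min(diff(series$wavelength))
  p0 <- spectrum_apex(series$wavelength, series$intensities[, 1])$position
  p1 <- spectrum_apex(series$wavelength,
                      series$intensities[, ncol(series$intensities)])$position
  delta <- p1 - p0
  direction <- if (abs(delta) <= threshold_nm) "none"
               else if (delta < 0) "blue" else "red"
  structure(list(direction = direction, magnitude_nm = abs(delta),
                 reference_nm = p0, final_nm = p1,
                 threshold_nm = threshold_nm),
            class = "peak_shift")
}

#' @export
print.peak_shift <- function(x, ...) {
  cat(sprintf("Peak shift: %s (%.2f nm; %.2f -> %.2f nm)\n",
              x$direction, x$magnitude_nm, x$reference_nm, x$final_nm))
  invisible(x)
}

#' Compare tyrosine vs tryptophan quenching contributions
#'
#' Pointwise comparison of the RSFQ ladders from the tyrosine
#' (delta-lambda = 15 nm) and tryptophan (delta-lambda = 60 nm) channels.
#' The residue whose RSFQ exceeds the other's (by more than `tolerance`)
#' at at least `majority` of the non-reference concentrations dominates
#' the quenching; otherwise the contributions are `"comparable"`.
#'
#' @param rsfq_tyr,rsfq_trp Data frames from [rsfq()] on the sync15 and
#'   sync60 series; concentration grids must match.
#' @param majority Fraction of points required for dominance; default 0.5
#'   (strict majority).
#' @param tolerance Minimum RSFQ difference counted as a win.
#' @return Object of class `"residue_dominance"` with element `dominant`
#'   (`"Trp"`, `"Tyr"` or `"comparable"`).
#' @export
residue_contribution <- function(rsfq_tyr, rsfq_trp, majority = 0.5,
                                 tolerance = 1e-6) {
  if (!isTRUE(all.equal(rsfq_tyr$concentration, rsfq_trp$concentration)))
    stop("concentration grids of the two channels do not match")
  keep <- rsfq_tyr$concentration > 0
  d <- rsfq_trp$rsfq[keep] - rsfq_tyr$rsfq[keep]
  n <- length(d)
  trp_wins <- sum(d > tolerance)
  tyr_wins <- sum(d < -tolerance)
  dominant <- if (trp_wins > majority * n) "Trp"
              else if (tyr_wins > majority * n) "Tyr"
              else "comparable"
  structure(list(dominant = dominant, trp_wins = trp_wins,
                 tyr_wins = tyr_wins, n = n, difference = d),
            class = "residue_dominance")
}

#' @export
print.residue_dominance <- function(x, ...) {
  cat(sprintf("Quenching contribution: %s (Trp ahead at %d/%d, Tyr at %d/%d)\n",
              x$dominant, x$trp_wins, x$n, x$tyr_wins, x$n))
  invisible(x)
}

#' Excitation-emission matrix
#'
#' @param ex_grid,em_grid Excitation/emission wavelength grids, nm,
#'   strictly increasing.
#' @param intensity Matrix indexed (excitation row, emission column).
#' @return Object of class `"eem"`.
#' @export
eem <- function(ex_grid, em_grid, intensity) {
  ex_grid <- as.numeric(ex_grid); em_grid <- as.numeric(em_grid)
  if (any(diff(ex_grid) <= 0) || any(diff(em_grid) <= 0))
    stop("EEM grids must be strictly increasing")
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == c(length(ex_grid), length(em_grid))))
    stop("intensity matrix must be (length(ex_grid) x length(em_grid))")
  stopifnot_finite(intensity, "EEM intensity")
  structure(list(ex_grid = ex_grid, em_grid = em_grid,
                 intensity = intensity),
            class = "eem")
}

#' Peak extraction from an excitation-emission matrix
#'
#' Masks the first-order Rayleigh ridge (`|Em - Ex| <= halfwidth`) and its
#' second order (`|Em - 2 Ex| <= halfwidth`), then returns the grid-local
#' maxima (8-neighborhood) above `min_prominence` of the unmasked global
#' maximum, sorted by decreasing intensity.
#'
#' @param x An [eem()].
#' @param scatter_halfwidth_nm Half-width of the scatter mask, nm;
#'   default 15.
#' @param min_prominence Intensity floor as a fraction of the unmasked
#'   maximum; default 0.05.
#' @return Data frame with columns `ex`, `em`, `intensity` (possibly
#'   zero rows; an all-masked matrix warns).
#' @export
eem_peaks <- function(x, scatter_halfwidth_nm = 15, min_prominence = 0.05) {
  stopifnot(inherits(x, "eem"))
  M <- x$intensity
  ex <- x$ex_grid; em <- x$em_grid
  mask <- outer(ex, em, function(e1, e2)
    abs(e2 - e1) <= scatter_halfwidth_nm |
      abs(e2 - 2 * e1) <= scatter_halfwidth_nm)
  W <- M
  W[mask] <- -Inf
  if (all(!is.finite(W))) {
    warning("entire matrix masked as scatter: no peaks")
    return(data.frame(ex = numeric(0), em = numeric(0),
                      intensity = numeric(0)))
  }
  floor_val <- max(W[is.finite(W)]) * min_prominence
  nr <- nrow(W); nc <- ncol(W)
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- W[i, j]
    if (!is.finite(v) || v < floor_val || v <= 0) next
    nb <- W[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (v >= max(nb)) out[[length(out) + 1L]] <-
        c(ex = ex[i], em = em[j], intensity = v)
  }
  if (!length(out))
    return(data.frame(ex = numeric(0), em = numeric(0),
                      intensity = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(-df$intensity), ]
  row.names(df) <- NULL
  df
}
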