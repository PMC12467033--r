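#' FTIR spectrum
#'
#' @param wavenumber Wavenumber grid, cm^-1, strictly monotone; must cover
#'   the amide-I window 1600-1700 cm^-1.
#' @param absorbance Absorbance values (finite).
#' @return Object of class `"ftir_spectrum"` (stored ascending).
#' @export
ftir_spectrum <- function(wavenumber, absorbance) {
  wavenumber <- as.numeric(wavenumber); absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance lengths differ")
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  if (all(d < 0)) {  # instruments often scan downward; store ascending
    wavenumber <- rev(wavenumber); absorbance <- rev(absorbance)
  }
  stopifnot_finite(absorbance, "absorbance")
  if (min(wavenumber) > 1600 || max(wavenumber) < 1700)
    stop("spectrum does not cover the amide-I window 1600-1700 cm^-1")
  structure(list(wavenumber = wavenumber, absorbance = absorbance),
            class = "ftir_spectrum")
}

# secondary-structure class ranges (cm^-1), closed-left cut points: the
# 1-wavenumber gaps between the printed ranges belong to the lower class
.amide_classes <- data.frame(
  klass = c("beta_sheet", "beta_antiparallel", "alpha_helix", "beta_turn",
            "random_coil"),
  lower = c(1615, 1638, 1649, 1661, 1681),
  upper = c(1638, 1649, 1661, 1681, 1692.0000001),
  stringsAsFactors = FALSE)

amide_class_of <- function(center) {
  vapply(center, function(cc) {
    i <- which(cc >= .amide_classes$lower & cc < .amide_classes$upper)
    if (length(i)) .amide_classes$klass[i] else "unassigned"
  }, character(1))
}

#' Extract the baseline-corrected amide-I band
#'
#' Restricts the spectrum to 1600-1700 cm^-1 and subtracts the straight
#' line through the two window endpoints.  Small negative residuals are
#' clipped to zero (their count is recorded).
#'
#' @param spec An [ftir_spectrum()].
#' @return Object of class `"amide_window"`: `wavenumber`, `absorbance`
#'   (baseline-removed), `baseline`, `n_clipped`.
#' @export
extract_amide_I <- function(spec) {
  stopifnot(inherits(spec, "ftir_spectrum"))
  keep <- spec$wavenumber >= 1600 & spec$wavenumber <= 1700
  w <- spec$wavenumber[keep]; a <- spec$absorbance[keep]
  slope <- (a[length(a)] - a[1]) / (w[length(w)] - w[1])
  base <- a[1] + slope * (w - w[1])
  y <- a - base
  n_clip <- sum(y < 0)
  y[y < 0] <- 0
  structure(list(wavenumber = w, absorbance = y, baseline = base,
                 n_clipped = n_clip),
            class = "amide_window")
}

gaussian_sum <- function(w, centers, sigmas, amps) {
  y <- numeric(length(w))
  for (k in seq_along(centers))
    y <- y + amps[k] * exp(-(w - centers[k])^2 / (2 * sigmas[k]^2))
  y
}

# candidate centers from minima of the smoothed second derivative
d2_candidates <- function(w, y, sg_window = 9, sg_order = 3) {
  h <- mean(diff(w))
  ys <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
  d2 <- signal::sgolayfilt(ys, p = sg_order, n = sg_window, m = 2) / h^2
  idx <- which(diff(sign(diff(d2))) > 0) + 1L  # local minima of d2
  idx <- idx[d2[idx] < 0 & y[idx] > 0.02 * max(y)]
  w[idx]
}

#' Deconvolute the amide-I band into Gaussian sub-peaks
#'
#' Fits a sum of Gaussians to the baseline-corrected amide-I window by
#' nonlinear least squares, with centers bounded to 1600-1700 cm^-1.
#' Seeding `"second_derivative"` places candidates at the negative minima
#' of the Savitzky-Golay-smoothed second derivative (the standard
#' band-narrowing heuristic); `"fixed_classes"` seeds one candidate at the
#' midpoint of each secondary-structure class range.
#'
#' @param windowed An [extract_amide_I()] result (or an
#'   [ftir_spectrum()], which is windowed first).
#' @param seeding `"second_derivative"` or `"fixed_classes"`.
#' @param sg_window,sg_order Savitzky-Golay smoothing window (points) and
#'   polynomial order for the second-derivative seeding.
#' @return Object of class `"amide_peaks"`: data frame `peaks` with
#'   columns `center`, `sigma`, `amplitude`, `area`
#'   (`amplitude * sigma * sqrt(2 pi)`) and `klass`, plus `rss` and
#'   `fitted`.
#' @export
deconvolve <- function(windowed,
                       seeding = c("second_derivative", "fixed_classes"),
                       sg_window = 9, sg_order = 3) {
  seeding <- match.arg(seeding)
  if (inherits(windowed, "ftir_spectrum")) windowed <- extract_amide_I(windowed)
  stopifnot(inherits(windowed, "amide_window"))
  w <- windowed$wavenumber; y <- windowed$absorbance
  if (max(y) <= 0) stop("degenerate signal: amide-I window is empty")

  centers0 <- if (seeding == "second_derivative")
    d2_candidates(w, y, sg_window, sg_order)
  else
    (.amide_classes$lower + pmin(.amide_classes$upper, 1692)) / 2
  if (!length(centers0)) centers0 <- w[which.max(y)]
  k <- length(centers0)
  sigma0 <- rep(6, k)
  amp0 <- pmax(stats::approx(w, y, xout = centers0, rule = 2)$y,
               0.05 * max(y))

  par0 <- c(centers0, sigma0, amp0)
  lower <- c(rep(1600, k), rep(1, k), rep(0, k))
  upper <- c(rep(1700, k), rep(40, k), rep(2 * max(y), k))
  resid_fn <- function(p) {
    gaussian_sum(w, p[1:k], p[(k + 1):(2 * k)], p[(2 * k + 1):(3 * k)]) - y
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, maxfev = 100000,
                         ftol = 1e-15, ptol = 1e-15, gtol = 1e-15)),
    error = function(e)
      stop(sprintf("amide-I deconvolution failed to converge: %s",
                   conditionMessage(e))))
  p <- fit$par
  centers <- p[1:k]; sigmas <- p[(k + 1):(2 * k)]
  amps <- p[(2 * k + 1):(3 * k)]
  keep <- amps > 1e-6 * max(y)   # drop collapsed components
  peaks <- data.frame(center = centers[keep], sigma = sigmas[keep],
                      amplitude = amps[keep],
                      area = amps[keep] * sigmas[keep] * sqrt(2 * pi))
  peaks$klass <- amide_class_of(peaks$center)
  peaks <- peaks[order(peaks$center), ]
  row.names(peaks) <- NULL
  if (nrow(peaks) < 1L) stop("no resolvable sub-peak in the amide-I window")
  structure(list(peaks = peaks, rss = sum(resid_fn(p)^2),
                 fitted = gaussian_sum(w, centers, sigmas, amps),
                 wavenumber = w),
            class = "amide_peaks")
}

#' @export
print.amide_peaks <- function(x, ...) {
  cat(sprintf("Amide-I deconvolution: %d sub-peaks (RSS = %.3g)\n",
              nrow(x$peaks), x$rss))
  print(cbind(round(x$peaks[, c("center", "sigma", "area")], 3),
              klass = x$peaks$klass), row.names = FALSE)
  invisible(x)
}

#' Secondary-structure percentages from amide-I sub-peaks
#'
#' Each sub-peak is assigned to a secondary-structure class by its center
#' wavenumber (alpha-helix 1649-1660, beta-sheet 1615-1637, beta-turn
#' 1661-1680, random coil 1681-1692, antiparallel beta-sheet 1638-1648
#' cm^-1; gaps closed left).  Class percentage = 100 x class area / total
#' assigned area.  Peaks whose centers fall outside all ranges are
#' reported as unassigned, excluded from the denominator, and warned
#' about.
#'
#' @param peaks An `"amide_peaks"` object from [deconvolve()], or a data
#'   frame with columns `center` and `area`.
#' @return Object of class `"secondary_structure"`: named `fractions`
#'   (percent, all five classes, summing to 100) and `unassigned_area`.
#' @export
#' @examples
#' pk <- data.frame(center = c(1620, 1670), area = c(2, 3))
#' assign_structure(pk)$fractions  # beta_sheet 40, beta_turn 60
assign_structure <- function(peaks) {
  df <- if (inherits(peaks, "amide_peaks")) peaks$peaks else peaks
  stopifnot(is.data.frame(df), all(c("center", "area") %in% names(df)),
            nrow(df) >= 1L)
  klass <- amide_class_of(df$center)
  unassigned <- sum(df$area[klass == "unassigned"])
  if (unassigned > 0)
    warning(sprintf(
      "%d sub-peak(s) outside the class ranges excluded from the denominator",
      sum(klass == "unassigned")))
  assigned <- df$area[klass != "unassigned"]
  if (sum(assigned) <= 0) stop("total assigned area is zero")
  total <- sum(assigned)
  fr <- vapply(.amide_classes$klass, function(kl)
    100 * sum(df$area[klass == kl]) / total, numeric(1))
  structure(list(fractions = fr, unassigned_area = unassigned),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure (% of amide-I area):\n")
  print(round(x$fractions, 2))
  invisible(x)
}
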