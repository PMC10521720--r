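# Search windows span both the 12C and the fully 13C-shifted positions,
# each printed endpoint +/- 6 cm^-1; the 1700-1800 cm^-1 region carries no
# carotenoid band and serves as the noise reference.
V1_WINDOW <- c(1490, 1540)
V2_WINDOW <- c(1130, 1170)
NOISE_WINDOW <- c(1700, 1800)
RATIO_WINDOW_12C <- c(1516, 1528)
RATIO_WINDOW_13C <- c(1496, 1508)

# Noise sd of a preprocessed spectrum, from the band-free 1700-1800 cm^-1
# region after removing a linear trend (robust to residual baseline).
noise_sd <- function(s) {
  w <- window_of(s, NOISE_WINDOW[1], NOISE_WINDOW[2])
  if (length(w$idx) < 8)
    stop("spectrum does not cover the noise reference region 1700-1800 cm^-1")
  stats::sd(stats::resid(stats::lm(w$intensity ~ w$wavenumber)))
}

#' Detect a carotenoid-containing cell
#'
#' A cell is carotenoid-positive iff both the nu1 (1490-1540 cm^-1) and nu2
#' (1130-1170 cm^-1) search windows contain a peak whose height exceeds
#' `min_snr` times the noise sd estimated from the band-free 1700-1800
#' cm^-1 region. The windows span both the 12C and the fully shifted band
#' positions, so fully labeled cells remain detectable.
#'
#' @param s A preprocessed [spectrum()] (baseline-corrected).
#' @param min_snr Minimum peak signal-to-noise ratio.
#' @return A list with `carotenoid` (logical), `snr_v1`, `snr_v2`,
#'   `noise_sd`.
#' @export
detect_carotenoid <- function(s, min_snr = 5) {
  ns <- noise_sd(s)
  peak_snr <- function(win) {
    w <- window_of(s, win[1], win[2])
    if (length(w$idx) == 0)
      stop("spectrum does not cover the band search windows")
    # peak height above the window median: robust to the positive offset
    # left by asymmetric baseline estimation
    height <- max(w$intensity) - stats::median(w$intensity)
    if (ns > 0) height / ns else if (height > 0) Inf else 0
  }
  s1 <- peak_snr(V1_WINDOW)
  s2 <- peak_snr(V2_WINDOW)
  list(carotenoid = s1 >= min_snr && s2 >= min_snr,
       snr_v1 = s1, snr_v2 = s2, noise_sd = ns)
}

# Lorentzian + constant offset least-squares fit over a window; seeded at
# the window argmax. Returns NULL on failure.
fit_lorentzian <- function(x, y, width0 = 12) {
  i0 <- which.max(y)
  start <- list(A = max(y[i0] - stats::median(y), 1e-6), ctr = x[i0],
                g = width0 / 2, b = stats::median(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A / (1 + ((x - ctr) / g)^2) + b,
      start = start,
      lower = c(A = 0, ctr = min(x), g = 0.5, b = -Inf),
      upper = c(A = Inf, ctr = max(x), g = (max(x) - min(x)), b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(center = unname(cf["ctr"]), height = unname(cf["A"]),
       fwhm = unname(2 * cf["g"]))
}

# 3-point parabolic interpolation of the maximum (fallback estimator).
parabolic_peak <- function(x, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(list(center = x[i], height = y[i]))
  num <- (y[i - 1] - y[i + 1]) / 2
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  d <- if (den != 0) num / den else 0
  step <- (x[i + 1] - x[i - 1]) / 2
  list(center = x[i] + d * step, height = y[i] - num * d / 2)
}

#' Estimate a band center by local Lorentzian fitting
#'
#' Least-squares Lorentzian fit (with a constant offset) inside the search
#' window, seeded at the window argmax; falls back to 3-point parabolic
#' interpolation of the maximum if the nonlinear fit fails. Returns
#' `ok = FALSE` when the window holds no peak above the noise.
#'
#' @param s A preprocessed [spectrum()].
#' @param window Wavenumber window `c(lo, hi)` inside the spectrum range.
#' @param band_name Band label carried into the result.
#' @param min_snr Peak SNR below which the fit is marked not-ok.
#' @return A `band_fit` list: `band`, `center`, `height`, `fwhm`, `snr`,
#'   `ok`, `method`.
#' @export
estimate_band_center <- function(s, window = V1_WINDOW, band_name = "v1",
                                 min_snr = 3) {
  w <- window_of(s, window[1], window[2])
  if (length(w$idx) < 5) stop("window outside (or barely inside) spectrum range")
  ns <- noise_sd(s)
  height0 <- max(w$intensity) - stats::median(w$intensity)
  snr <- if (ns > 0) height0 / ns else if (height0 > 0) Inf else 0
  if (snr < min_snr) {
    return(structure(list(band = band_name, center = NA_real_,
                          height = NA_real_, fwhm = NA_real_, snr = snr,
                          ok = FALSE, method = "none"), class = "band_fit"))
  }
  fit <- fit_lorentzian(w$wavenumber, w$intensity)
  in_window <- !is.null(fit) && fit$center > window[1] && fit$center < window[2]
  if (in_window) {
    res <- list(band = band_name, center = fit$center, height = fit$height,
                fwhm = fit$fwhm, snr = snr, ok = TRUE, method = "lorentzian")
  } else {
    pk <- parabolic_peak(w$wavenumber, w$intensity)
    res <- list(band = band_name, center = pk$center, height = pk$height,
                fwhm = NA_real_, snr = snr, ok = TRUE, method = "parabolic")
  }
  structure(res, class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<band_fit> %s: center %.2f cm^-1, fwhm %.1f, snr %.1f (%s)\n",
                x$band, x$center, x$fwhm, x$snr, x$method))
  else
    cat(sprintf("<band_fit> %s: no peak (snr %.1f)\n", x$band, x$snr))
  invisible(x)
}

#' Band shifts and the nu1 intensity-ratio statistic for one cell
#'
#' Shift = reference 12C center minus observed center per band, so a
#' positive value is a red shift (toward lower wavenumber). The intensity
#' ratio is `A13 / (A12 + A13)` where `A12` and `A13` are trapezoid
#' integrals of the baseline-corrected intensity over the 12C nu1 window
#' (1516-1528 cm^-1) and the fully shifted nu1 window (1496-1508 cm^-1);
#' negative integrals (pure noise) are clipped at zero so the ratio stays
#' in \[0, 1\]. The ratio is monotone in the labeled fraction and unit-free.
#'
#' @param s The preprocessed [spectrum()] (used for the ratio integrals).
#' @param reference A list/row with the per-band 12C mean centers, e.g.
#'   `list(v1 = 1522, v2 = 1158)` or a `sip_reference` from
#'   [build_reference()].
#' @param fits Optional precomputed list `list(v1 = , v2 = )` of
#'   [estimate_band_center()] results; computed if missing.
#' @return A list: `v1_center`, `v2_center`, `v1_shift`, `v2_shift`,
#'   `v1_ratio`, `ok`.
#' @export
compute_shift <- function(s, reference, fits = NULL) {
  ref1 <- ref_center(reference, "v1")
  ref2 <- ref_center(reference, "v2")
  if (is.null(fits))
    fits <- list(v1 = estimate_band_center(s, V1_WINDOW, "v1"),
                 v2 = estimate_band_center(s, V2_WINDOW, "v2"))
  a12 <- max(0, trapz_window(s, RATIO_WINDOW_12C[1], RATIO_WINDOW_12C[2]))
  a13 <- max(0, trapz_window(s, RATIO_WINDOW_13C[1], RATIO_WINDOW_13C[2]))
  ratio <- if (a12 + a13 > 0) a13 / (a12 + a13) else NA_real_
  list(v1_center = fits$v1$center, v2_center = fits$v2$center,
       v1_shift = ref1 - fits$v1$center, v2_shift = ref2 - fits$v2$center,
       v1_ratio = ratio, ok = fits$v1$ok && fits$v2$ok)
}

# Accept a plain list(v1=, v2=) of centers or a sip_reference object.
ref_center <- function(reference, band) {
  if (inherits(reference, "sip_reference")) return(reference$mean[[band]])
  v <- reference[[band]]
  if (is.null(v)) stop("reference is missing band ", band)
  if (is.list(v)) v$mean else as.numeric(v)
}

#' Channel-wise mean spectrum with standard deviation
#'
#' All spectra must share a common wavenumber grid (use
#' [resample_spectrum()] first); channels flagged missing in a cell are
#' excluded from that channel's mean and sd, never zero-filled.
#'
#' @param cells List of [spectrum()] objects on a common grid.
#' @return A list with `mean` (a [spectrum()]), `sd` (numeric vector) and
#'   `n` (per-channel cell counts).
#' @export
average_spectrum <- function(cells) {
  if (length(cells) == 0) stop("no cells to average")
  grid <- cells[[1]]$wavenumber
  for (s in cells)
    if (!isTRUE(all.equal(s$wavenumber, grid)))
      stop("all spectra must share a common grid; resample first")
  m <- do.call(rbind, lapply(cells, function(s) s$intensity))
  structure(
    list(mean = spectrum(grid, colMeans(m, na.rm = TRUE), cell_id = "mean"),
         sd = apply(m, 2, stats::sd, na.rm = TRUE),
         n = colSums(!is.na(m))),
    class = "raman_mean_spectrum")
}

#' @export
print.raman_mean_spectrum <- function(x, ...) {
  cat(sprintf("<raman_mean_spectrum> mean of up to %d cells, %d channels\n",
              max(x$n), length(x$n)))
  invisible(x)
}

#' Plot a mean spectrum with its standard-deviation band
#' @param x An [average_spectrum()] result.
#' @param ... Passed to the underlying line plot.
#' @export
plot.raman_mean_spectrum <- function(x, ...) {
  wn <- x$mean$wavenumber
  mu <- x$mean$intensity
  ok <- !is.na(mu) & !is.na(x$sd)
  graphics::plot(wn, mu, type = "n",
                 xlab = expression(paste("Wavenumber (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)", ...)
  graphics::polygon(c(wn[ok], rev(wn[ok])),
                    c(mu[ok] + x$sd[ok], rev(mu[ok] - x$sd[ok])),
                    border = NA, col = grDevices::rgb(0.2, 0.4, 0.8, 0.3))
  graphics::lines(wn, mu)
  invisible(x)
}

#' Histogram of band shifts across carotenoid-positive cells
#'
#' Bins are left-closed, right-open, aligned at 0; the total count equals
#' the number of carotenoid-positive cells with a valid fit.
#'
#' @param shifts Numeric vector of per-cell shifts in cm^-1 (e.g. the
#'   `v1_shift` column of [analyze_bands()] restricted to
#'   carotenoid-positive cells).
#' @param bin_width Bin width in cm^-1.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
shift_histogram <- function(shifts, bin_width = 2) {
  shifts <- shifts[is.finite(shifts)]
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (length(shifts) == 0)
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer()))
  idx <- floor(shifts / bin_width)
  tab <- table(idx)
  lo <- as.numeric(names(tab)) * bin_width
  data.frame(bin_lo = lo, bin_hi = lo + bin_width,
             count = as.integer(tab), row.names = NULL)
}

#' Per-cell band analysis table
#'
#' Runs carotenoid detection, nu1/nu2 band fitting and shift/ratio
#' computation for every cell and returns one row per cell, the table the
#' sorting classifier consumes.
#'
#' @param cells List of preprocessed [spectrum()] objects.
#' @param reference Per-band 12C reference centers (see [compute_shift()]);
#'   `NULL` returns centers without shifts.
#' @param min_snr Detection threshold, see [detect_carotenoid()].
#' @return data.frame with columns `cell_id`, `carotenoid`, `v1_center`,
#'   `v2_center`, `v1_fwhm`, `v2_fwhm`, `v1_snr`, `v2_snr`, `v1_shift`,
#'   `v2_shift`, `v1_ratio`, plus truth columns `true_f`/`species`/`day`
#'   when present in the cell metadata.
#' @export
analyze_bands <- function(cells, reference = NULL, min_snr = 5) {
  if (length(cells) == 0)
    return(data.frame(cell_id = character(), carotenoid = logical(),
                      v1_center = numeric(), v2_center = numeric(),
                      v1_fwhm = numeric(), v2_fwhm = numeric(),
                      v1_snr = numeric(), v2_snr = numeric(),
                      v1_shift = numeric(), v2_shift = numeric(),
                      v1_ratio = numeric(), true_f = numeric(),
                      species = character(), day = numeric()))
  rows <- lapply(cells, function(s) {
    det <- detect_carotenoid(s, min_snr = min_snr)
    f1 <- estimate_band_center(s, V1_WINDOW, "v1")
    f2 <- estimate_band_center(s, V2_WINDOW, "v2")
    sh <- if (!is.null(reference))
      compute_shift(s, reference, fits = list(v1 = f1, v2 = f2))
    else list(v1_shift = NA_real_, v2_shift = NA_real_, v1_ratio = NA_real_)
    data.frame(
      cell_id = s$cell_id, carotenoid = det$carotenoid,
      v1_center = f1$center, v2_center = f2$center,
      v1_fwhm = f1$fwhm, v2_fwhm = f2$fwhm,
      v1_snr = f1$snr, v2_snr = f2$snr,
      v1_shift = sh$v1_shift, v2_shift = sh$v2_shift,
      v1_ratio = sh$v1_ratio,
      true_f = s$meta$true_f %||% NA_real_,
      species = s$meta$species %||% NA_character_,
      day = s$meta$day %||% NA_real_)
  })
  do.call(rbind, rows)
}
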