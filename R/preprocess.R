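#' Remove cosmic-ray spikes from a spectrum
#'
#' Rolling modified z-score despiking: each channel is compared with the
#' median of a centered window using the median/MAD z-score
#' `0.6745 * (x - median) / MAD`, which is robust to the band peaks
#' themselves; channels exceeding `z_thresh` are replaced by the window
#' median, all others are untouched. Idempotent on spike-free input.
#'
#' @param s A [spectrum()].
#' @param window Odd window size in channels (>= 3).
#' @param z_thresh Modified z-score threshold.
#' @return The despiked spectrum.
#' @export
despike <- function(s, window = 7, z_thresh = 6) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  n <- length(s$intensity)
  if (window > n) stop("`window` larger than the spectrum")
  y <- s$intensity
  out <- y
  half <- (window - 1) / 2
  # centered-window medians/MADs; interior windows handled as one sorted
  # matrix sweep, partial edge windows individually
  interior <- (half + 1):(n - half)
  emb <- matrix(y[outer(interior - half, 0:(window - 1), `+`)],
                nrow = length(interior))
  med <- rep(NA_real_, n)
  madv <- rep(NA_real_, n)
  med[interior] <- apply(emb, 1, stats::median, na.rm = TRUE)
  madv[interior] <- apply(abs(emb - med[interior]), 1, stats::median,
                          na.rm = TRUE)
  for (i in c(seq_len(half), (n - half + 1):n)) {
    w <- y[max(1, i - half):min(n, i + half)]
    med[i] <- stats::median(w, na.rm = TRUE)
    madv[i] <- stats::median(abs(w - med[i]), na.rm = TRUE)
  }
  dev <- abs(y - med)
  z <- ifelse(madv > 0, 0.6745 * dev / madv, ifelse(dev > 0, Inf, 0))
  replace <- !is.na(z) & z > z_thresh
  out[replace] <- med[replace]
  set_intensity(s, out)
}

# Asymmetric least squares baseline (Whittaker smoother with asymmetric
# weights): minimizes sum(w * (y - z)^2) + lam * sum(diff(z, 2)^2), with
# w = p above the baseline and 1 - p below, iterated to convergence.
als_baseline <- function(y, lam = 1e5, p = 0.01, max_iter = 30, tol = 1e-8) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lam * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(m, w)
    z_new <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z_new, p, 1 - p)
    done <- all(w_new == w)
    w <- w_new
    z <- z_new
    if (done && it > 1) return(list(baseline = z, converged = TRUE))
  }
  list(baseline = z, converged = FALSE)
}

#' Subtract the fluorescence baseline
#'
#' Removes a smooth estimated background. The default `"als"` method is the
#' asymmetric least squares (Whittaker) smoother, suited to the smooth
#' positive fluorescence backgrounds of pigmented cells; the `"polynomial"`
#' method fits an ordinary polynomial by least squares and is exact on pure
#' polynomial input of degree <= `degree`.
#'
#' @param s A [spectrum()].
#' @param method `"als"` or `"polynomial"`.
#' @param lam,p,max_iter ALS parameters: roughness penalty, asymmetry
#'   weight, iteration cap.
#' @param degree Polynomial degree (<= 6) for the polynomial method.
#' @return The baseline-corrected spectrum.
#' @export
baseline_correct <- function(s, method = c("als", "polynomial"),
                             lam = 1e5, p = 0.01, max_iter = 30, degree = 3) {
  stopifnot(inherits(s, "raman_spectrum"))
  method <- match.arg(method)
  y <- s$intensity
  ok <- !is.na(y)
  if (!any(ok)) return(s)
  if (all(y[ok] == 0)) return(s)
  if (method == "polynomial") {
    if (degree < 0 || degree > 6) stop("`degree` must be in 0..6")
    x <- s$wavenumber[ok]
    fit <- stats::lm(y[ok] ~ stats::poly(x, degree = max(degree, 1), raw = TRUE))
    base <- stats::fitted(fit)
  } else {
    if (lam <= 0 || p <= 0 || p >= 1) stop("ALS needs lam > 0 and p in (0, 1)")
    res <- als_baseline(y[ok], lam = lam, p = p, max_iter = max_iter)
    if (!res$converged)
      warning(sprintf("ALS baseline did not converge for cell '%s'", s$cell_id))
    base <- res$baseline
  }
  y[ok] <- y[ok] - base
  set_intensity(s, y)
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial smoothing; exact (to machine precision) on polynomial
#' input of degree <= `polyorder`, including the end channels. `window = 1`
#' is the identity.
#'
#' @param s A [spectrum()].
#' @param window Odd window length in channels.
#' @param polyorder Local polynomial order (< window).
#' @return The smoothed spectrum.
#' @export
smooth_spectrum <- function(s, window = 7, polyorder = 3) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (window == 1) return(s)
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be < window")
  y <- s$intensity
  ok <- !is.na(y)
  y[ok] <- signal::sgolayfilt(y[ok], p = polyorder, n = window)
  set_intensity(s, y)
}

#' Normalize a spectrum
#'
#' `"max"` mode scales so the maximum intensity inside the nu1 search
#' window (default 1490-1540 cm^-1) equals 1, enabling overlay of spectra
#' acquired at different laser powers; `"area"` mode scales so the
#' trapezoidal integral over the full axis equals 1. Both preserve shape
#' (channel ratios). A spectrum with no positive normalization constant is
#' an error, never a division by zero.
#'
#' @param s A [spectrum()].
#' @param mode `"max"` or `"area"`.
#' @param window Wavenumber window for `"max"` mode.
#' @return The normalized spectrum.
#' @export
normalize_spectrum <- function(s, mode = c("max", "area"),
                               window = c(1490, 1540)) {
  stopifnot(inherits(s, "raman_spectrum"))
  mode <- match.arg(mode)
  if (mode == "max") {
    w <- window_of(s, window[1], window[2])
    if (length(w$idx) == 0) stop("normalization window outside spectrum range")
    const <- max(w$intensity)
  } else {
    y <- s$intensity
    ok <- !is.na(y)
    x <- s$wavenumber[ok]; yy <- y[ok]
    const <- sum(diff(x) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  }
  if (!is.finite(const) || const <= 0)
    stop(sprintf("cannot normalize cell '%s': non-positive normalization constant",
                 s$cell_id))
  set_intensity(s, s$intensity / const)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; target points outside the source wavenumber range
#' are flagged missing (`NA`), never extrapolated. Downstream averaging
#' ignores missing channels.
#'
#' @param s A [spectrum()].
#' @param grid Strictly increasing target wavenumber grid.
#' @return The resampled spectrum.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "raman_spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing")
  ok <- !is.na(s$intensity)
  y <- stats::approx(s$wavenumber[ok], s$intensity[ok], xout = grid,
                     method = "linear", rule = 1)$y
  spectrum(grid, y, cell_id = s$cell_id, meta = s$meta)
}

#' Standard preprocessing pipeline
#'
#' Applies despike, baseline correction, Savitzky-Golay smoothing and (by
#' default) nu1-window max normalization, in that order.
#'
#' @param s A [spectrum()].
#' @param despike_window,despike_z See [despike()].
#' @param baseline_method,lam,p,degree See [baseline_correct()].
#' @param smooth_window,smooth_polyorder See [smooth_spectrum()].
#' @param normalize `"max"`, `"area"` or `"none"`.
#' @return The preprocessed spectrum.
#' @export
preprocess_spectrum <- function(s, despike_window = 7, despike_z = 6,
                                baseline_method = "als", lam = 1e5, p = 0.01,
                                degree = 3, smooth_window = 7,
                                smooth_polyorder = 3, normalize = "max") {
  s <- despike(s, window = despike_window, z_thresh = despike_z)
  s <- baseline_correct(s, method = baseline_method, lam = lam, p = p,
                        degree = degree)
  s <- smooth_spectrum(s, window = smooth_window, polyorder = smooth_polyorder)
  if (normalize != "none") s <- normalize_spectrum(s, mode = normalize)
  s
}

#' Preprocess a list of cells
#' @param cells List of [spectrum()] objects.
#' @param ... Passed to [preprocess_spectrum()].
#' @return List of preprocessed spectra.
#' @export
preprocess_cells <- function(cells, ...) lapply(cells, preprocess_spectrum, ...)
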