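#' Construct a single-cell Raman spectrum
#'
#' A spectrum is a wavenumber axis with matched intensities for one cell.
#' Intensities may contain `NA` after [resample_spectrum()] for grid points
#' outside the source range; such channels are treated as missing, never as
#' zero, by downstream averaging.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, length >= 16.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumber`. Finite or `NA` (missing).
#' @param cell_id Character scalar identifying the cell.
#' @param meta Named list of free-form metadata (timepoint, treatment,
#'   simulation ground truth, ...).
#' @return An object of class `raman_spectrum`.
#' @export
#' @examples
#' s <- spectrum(600:1800, rexp(1201), cell_id = "cell_1")
#' print(s)
spectrum <- function(wavenumber, intensity, cell_id = "cell", meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("`wavenumber` and `intensity` must have the same length")
  if (length(wavenumber) < 16L)
    stop("a spectrum needs at least 16 channels")
  if (any(!is.finite(wavenumber)) || any(diff(wavenumber) <= 0))
    stop("`wavenumber` must be finite and strictly increasing")
  if (any(is.infinite(intensity)) || any(is.nan(intensity)))
    stop("`intensity` must be finite (NA allowed for missing channels)")
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         cell_id = as.character(cell_id), meta = meta),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> cell '%s': %d channels, %.0f-%.0f cm^-1\n",
              x$cell_id, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  truth <- x$meta[c("is_carotenoid", "true_f", "species", "day")]
  truth <- truth[!vapply(truth, is.null, logical(1))]
  if (length(truth))
    cat("  meta:", paste(names(truth), unlist(truth), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumber, x$intensity, type = "l",
                 xlab = expression(paste("Wavenumber (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)", main = x$cell_id, ...)
  invisible(x)
}

# Intensity values of `s` restricted to [lo, hi] cm^-1 (with wavenumbers).
window_of <- function(s, lo, hi) {
  i <- which(s$wavenumber >= lo & s$wavenumber <= hi & !is.na(s$intensity))
  list(wavenumber = s$wavenumber[i], intensity = s$intensity[i], idx = i)
}

# Replace intensities, keeping axis and metadata.
set_intensity <- function(s, y) {
  s$intensity <- y
  s
}

#' Trapezoidal integral of a spectrum over a wavenumber window
#' @noRd
trapz_window <- function(s, lo, hi) {
  w <- window_of(s, lo, hi)
  if (length(w$idx) < 2L) return(0)
  sum(diff(w$wavenumber) * (utils::head(w$intensity, -1) + utils::tail(w$intensity, -1)) / 2)
}
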