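#' Carotenoid Raman band shift model
#'
#' Describes, for each carotenoid resonance Raman band, the band center of a
#' fully 12C cell, the center of a fully 13C-labeled cell, and the line width
#' and relative amplitude used by the spectrum simulator. 13C incorporation
#' displaces each center to lower wavenumber (a red shift), so
#' `center13 <= center12` is enforced for every band.
#'
#' @param bands A data.frame with columns `band` (unique names), `center12`,
#'   `center13` (cm^-1), `width` (FWHM, cm^-1, > 0) and `amplitude`
#'   (relative intensity, >= 0).
#' @return An object of class `band_model` (a validated data.frame).
#' @seealso [default_band_model()], [band_center()]
#' @export
band_model <- function(bands) {
  bands <- as.data.frame(bands)
  need <- c("band", "center12", "center13", "width", "amplitude")
  if (!all(need %in% names(bands)))
    stop("`bands` must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(bands$band)) stop("band names must be unique")
  if (any(bands$center13 > bands$center12))
    stop("center13 must be <= center12 for every band (13C red shift)")
  if (any(bands$width <= 0)) stop("band widths must be positive")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be non-negative")
  rownames(bands) <- bands$band
  structure(bands, class = c("band_model", "data.frame"))
}

#' Default carotenoid band model
#'
#' The nu1 (in-phase C=C stretch) and nu2 (C-C polyene stretch) endpoints are
#' the published positions for marine carotenoid-containing cells: nu1 shifts
#' from 1522 cm^-1 (12C) to ~1502 cm^-1 at full labeling, nu2 from 1158 to
#' ~1145 cm^-1. nu3 (CH3 in-plane rock) is included at its literature
#' position ~1004 cm^-1 with a small shift to 1000 cm^-1; nu3 is simulated
#' but never used by the classifier. Widths default to 12 cm^-1 FWHM and
#' amplitudes to 1.0 : 0.6 : 0.3, typical of carotenoid resonance Raman
#' profiles; only relative intensities matter downstream.
#'
#' @return A `band_model` with bands `v1`, `v2`, `v3`.
#' @export
#' @examples
#' m <- default_band_model()
#' band_center(m, "v1", 0.5)  # 1512 cm^-1, the day-1 position
default_band_model <- function() {
  band_model(data.frame(
    band = c("v1", "v2", "v3"),
    center12 = c(1522, 1158, 1004),
    center13 = c(1502, 1145, 1000),
    width = c(12, 12, 12),
    amplitude = c(1.0, 0.6, 0.3)))
}

#' Band center at a given 13C fraction
#'
#' Linear mixing model: the observed center of a band interpolates between
#' its 12C and fully labeled endpoints with the cell's 13C fraction `f`,
#' `center(f) = center12 - f * (center12 - center13)`. The function is exactly
#' linear and monotone non-increasing in `f`.
#'
#' @param model A [band_model()].
#' @param band Band name, e.g. `"v1"`.
#' @param f 13C fraction in \[0, 1\] (vectorized).
#' @return Band center(s) in cm^-1.
#' @export
band_center <- function(model, band, f) {
  stopifnot(inherits(model, "band_model"))
  if (!band %in% model$band) stop("unknown band: ", band)
  if (any(f < 0 | f > 1)) stop("`f` must be in [0, 1]")
  b <- model[model$band == band, ]
  b$center12 - f * (b$center12 - b$center13)
}

#' Estimate the 13C fraction from an observed band center
#'
#' Inverts the linear band-shift model:
#' `f = (center12 - center_obs) / (center12 - center13)`, clipped to
#' \[0, 1\]. Composed with [band_center()] this is the identity on \[0, 1\]
#' up to machine precision.
#'
#' @param center_obs Observed band center in cm^-1 (vectorized).
#' @param model A [band_model()].
#' @param band Band name.
#' @return Estimated 13C fraction(s) in \[0, 1\].
#' @export
#' @examples
#' estimate_f(1512, band = "v1")  # 0.5
estimate_f <- function(center_obs, model = default_band_model(), band = "v1") {
  stopifnot(inherits(model, "band_model"))
  if (!band %in% model$band) stop("unknown band: ", band)
  b <- model[model$band == band, ]
  if (b$center12 == b$center13) stop("band endpoints must be distinct")
  pmin(1, pmax(0, (b$center12 - center_obs) / (b$center12 - b$center13)))
}
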