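#' Spectrum simulation parameters
#'
#' Instrument-like forward model behind the synthetic single-cell Raman
#' spectra: a wavenumber grid, a signal-to-noise ratio defined as the nu1
#' peak height divided by the additive Gaussian noise sd, a smooth
#' polynomial fluorescence background, and a Poisson rate of cosmic-ray
#' spikes per spectrum.
#'
#' @param grid_min,grid_max,grid_step Wavenumber grid in cm^-1. The default
#'   600-1800 cm^-1 at 1 cm^-1 steps covers all three carotenoid bands at
#'   instrument-like resolution.
#' @param snr Dimensionless; nu1 peak height / noise sd. `Inf` gives a
#'   noise-free spectrum.
#' @param baseline_coeffs Polynomial coefficients (intercept first) of the
#'   fluorescence background, evaluated in the rescaled coordinate
#'   `(wavenumber - grid_min) / (grid_max - grid_min)`. The default gives a
#'   smooth positive background comparable in magnitude to the band peaks,
#'   as is typical of pigmented cells.
#' @param spike_rate Expected number of cosmic-ray spikes per spectrum.
#' @return An object of class `spectrum_sim_params`.
#' @export
spectrum_sim_params <- function(grid_min = 600, grid_max = 1800, grid_step = 1,
                                snr = 20, baseline_coeffs = c(0.6, 0.4, -0.35),
                                spike_rate = 0.1) {
  if (grid_min >= grid_max) stop("grid_min must be < grid_max")
  if (grid_step <= 0) stop("grid_step must be positive")
  if (!(snr > 0)) stop("snr must be positive")
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  structure(list(grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step, snr = snr,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 spike_rate = spike_rate),
            class = "spectrum_sim_params")
}

#' Labeling kinetics parameters
#'
#' Population-mean 13C fraction over incubation time, with per-cell
#' heterogeneity that shrinks as the population approaches steady state.
#' The mean follows a saturating sigmoidal (Weibull-type) curve
#' `f_mean(t) = f_max * (1 - exp(-(k * t)^shape))`: cells need to switch to
#' active fixation before label accumulates, so uptake accelerates after an
#' initial lag and then saturates. Defaults are calibrated so that the
#' population mean is half-labeled at day 1 and within 5% of the plateau by
#' day 2 (48 h), matching the observed time course: `shape = 2.5` and
#' `k = log(2)^(1/2.5)` per day give `f_mean(1) = 0.5` and
#' `f_mean(2) = 0.98`.
#' Per-cell fractions at day t are drawn as
#' `Normal(f_mean(t), heterogeneity_sd0 * heterogeneity_decay^(t - 1))`
#' clipped to \[0, f_max\]; day 0 cells are exactly unlabeled.
#'
#' @param f_max Plateau 13C fraction in \[0, 1\].
#' @param k Rate constant per day.
#' @param shape Weibull shape (>= 1); 1 recovers simple exponential
#'   saturation.
#' @param heterogeneity_sd0 sd of the per-cell 13C fraction at day 1.
#' @param heterogeneity_decay Per-day multiplicative decay of that sd.
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(f_max = 1.0, k = log(2)^0.4, shape = 2.5,
                            heterogeneity_sd0 = 0.15,
                            heterogeneity_decay = 0.3) {
  assert_fraction(f_max, "f_max")
  if (!(k > 0)) stop("k must be positive")
  if (!(shape >= 1)) stop("shape must be >= 1")
  if (heterogeneity_sd0 < 0 || heterogeneity_decay < 0)
    stop("heterogeneity parameters must be >= 0")
  structure(list(f_max = f_max, k = k, shape = shape,
                 heterogeneity_sd0 = heterogeneity_sd0,
                 heterogeneity_decay = heterogeneity_decay),
            class = "kinetics_params")
}

#' Population-mean 13C fraction at time t
#' @param kin A [kinetics_params()].
#' @param t Time in days (vectorized).
#' @return Mean 13C fraction(s).
#' @export
f_mean <- function(kin, t) {
  stopifnot(inherits(kin, "kinetics_params"))
  kin$f_max * (1 - exp(-(kin$k * t)^kin$shape))
}

lorentzian <- function(x, center, fwhm, amplitude) {
  amplitude / (1 + ((x - center) / (fwhm / 2))^2)
}

#' Simulate one single-cell carotenoid Raman spectrum
#'
#' Forward model: a sum of Lorentzian bands at the centers given by
#' [band_center()] for the cell's 13C fraction, plus a smooth polynomial
#' fluorescence baseline, i.i.d. Gaussian noise of sd = (nu1 amplitude)/snr,
#' and a Poisson number of single-channel cosmic-ray spikes. Identical seeds
#' give identical spectra.
#'
#' @param model A [band_model()]; set all amplitudes to 0 for a
#'   non-carotenoid cell.
#' @param f 13C fraction in \[0, 1\].
#' @param sim A [spectrum_sim_params()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param cell_id Cell identifier stored in the spectrum.
#' @return A [spectrum()] whose `meta` records `true_f` and `is_carotenoid`.
#' @export
#' @examples
#' s <- simulate_spectrum(f = 0.5, seed = 1)
#' plot(s)
simulate_spectrum <- function(model = default_band_model(), f = 0,
                              sim = spectrum_sim_params(), seed = NULL,
                              cell_id = "cell") {
  stopifnot(inherits(model, "band_model"), inherits(sim, "spectrum_sim_params"))
  assert_fraction(f, "f")
  x <- seq(sim$grid_min, sim$grid_max, by = sim$grid_step)
  if (length(x) < 16L) stop("degenerate grid: fewer than 16 channels")
  signal <- rep(0, length(x))
  for (b in model$band) {
    row <- model[model$band == b, ]
    if (row$amplitude > 0)
      signal <- signal +
        lorentzian(x, band_center(model, b, f), row$width, row$amplitude)
  }
  u <- (x - sim$grid_min) / (sim$grid_max - sim$grid_min)
  baseline <- drop(outer(u, seq_along(sim$baseline_coeffs) - 1, `^`) %*%
                     sim$baseline_coeffs)
  amp_ref <- model["v1", "amplitude"]
  if (is.na(amp_ref) || amp_ref <= 0) amp_ref <- 1
  noise_sd <- if (is.infinite(sim$snr)) 0 else amp_ref / sim$snr
  with_seed(seed, {
    y <- signal + baseline + stats::rnorm(length(x), 0, noise_sd)
    n_spikes <- stats::rpois(1, sim$spike_rate)
    if (n_spikes > 0) {
      at <- sample.int(length(x), n_spikes, replace = TRUE)
      y[at] <- y[at] + stats::runif(n_spikes, 10, 50) * amp_ref
    }
    spectrum(x, y, cell_id = cell_id,
             meta = list(true_f = f,
                         is_carotenoid = any(model$amplitude > 0)))
  })
}

zero_amplitude <- function(model) {
  model$amplitude[] <- 0
  band_model(as.data.frame(model))
}

#' Simulate a population of single cells
#'
#' Generates a mixture of carotenoid-containing and non-carotenoid cells,
#' with a fraction of the carotenoid cells 13C-labeled. Class counts are
#' rounded deterministically: `floor(n_cells * carotenoid_fraction)` cells
#' are carotenoid-containing, and `floor(n_carotenoid * labeled_fraction)`
#' of those are labeled; non-carotenoid cells have zero band amplitudes and
#' `true_f = 0`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param carotenoid_fraction,labeled_fraction Fractions in \[0, 1\].
#' @param f_dist 13C fraction of labeled cells: either a single number
#'   (point mass) or a `function(n)` returning `n` draws in \[0, 1\].
#' @param model,sim See [simulate_spectrum()].
#' @param seed Integer seed.
#' @param species Species tag stored in each cell's metadata.
#' @param id_prefix Prefix for generated cell ids.
#' @return List of [spectrum()] objects carrying ground truth in `meta`
#'   (`is_carotenoid`, `labeled`, `true_f`, `species`).
#' @export
simulate_population <- function(n_cells, carotenoid_fraction = 1,
                                labeled_fraction = 0, f_dist = 0.5,
                                model = default_band_model(),
                                sim = spectrum_sim_params(), seed = NULL,
                                species = "species_1", id_prefix = "cell") {
  stopifnot(n_cells >= 1)
  assert_fraction(carotenoid_fraction, "carotenoid_fraction")
  assert_fraction(labeled_fraction, "labeled_fraction")
  n_car <- floor(n_cells * carotenoid_fraction)
  n_lab <- floor(n_car * labeled_fraction)
  draw_f <- if (is.function(f_dist)) f_dist else function(n) rep(f_dist, n)
  seeds <- derive_seeds(seed, n_cells + 1L)
  fs <- with_seed(seeds[[n_cells + 1L]], {
    f <- pmin(1, pmax(0, draw_f(n_lab)))
    if (length(f) != n_lab) stop("f_dist returned wrong length")
    f
  })
  no_band <- zero_amplitude(model)
  lapply(seq_len(n_cells), function(i) {
    car <- i <= n_car
    lab <- car && i <= n_lab
    s <- simulate_spectrum(model = if (car) model else no_band,
                           f = if (lab) fs[i] else 0,
                           sim = sim, seed = seeds[[i]],
                           cell_id = sprintf("%s_%03d", id_prefix, i))
    s$meta$species <- species
    s$meta$labeled <- lab
    s
  })
}

#' Simulate a mock community
#'
#' Multi-species population in stated proportions, mirroring a defined
#' mixture in which only the autotrophic species incorporates
#' 13C-bicarbonate while a carotenoid-containing heterotroph and a
#' non-carotenoid yeast remain unlabeled. No cross-feeding is modeled.
#'
#' @param n_cells Total number of cells; split across species by
#'   deterministic rounding (floor, remainder to the last species).
#' @param species A data.frame with columns `name`, `proportion`,
#'   `carotenoid` (logical), `labeled` (logical), `f` (13C fraction of
#'   labeled cells). Default: three species mixed 1:1:1 with only the
#'   autotroph labeled at f = 0.5.
#' @param model,sim,seed See [simulate_population()].
#' @return List of [spectrum()] objects with per-cell `species` truth.
#' @export
simulate_mock_community <- function(n_cells,
                                    species = data.frame(
                                      name = c("autotroph", "heterotroph",
                                               "yeast"),
                                      proportion = 1 / 3,
                                      carotenoid = c(TRUE, TRUE, FALSE),
                                      labeled = c(TRUE, FALSE, FALSE),
                                      f = c(0.5, 0, 0)),
                                    model = default_band_model(),
                                    sim = spectrum_sim_params(),
                                    seed = NULL) {
  stopifnot(n_cells >= nrow(species), all(species$proportion >= 0))
  counts <- floor(n_cells * species$proportion / sum(species$proportion))
  counts[nrow(species)] <- counts[nrow(species)] + n_cells - sum(counts)
  seeds <- derive_seeds(seed, nrow(species))
  cells <- vector("list", 0)
  for (i in seq_len(nrow(species))) {
    if (counts[i] == 0) next
    pop <- simulate_population(
      n_cells = counts[i],
      carotenoid_fraction = as.numeric(species$carotenoid[i]),
      labeled_fraction = as.numeric(species$labeled[i]),
      f_dist = species$f[i], model = model, sim = sim, seed = seeds[[i]],
      species = species$name[i], id_prefix = species$name[i])
    cells <- c(cells, pop)
  }
  cells
}

#' Simulate a labeling time course
#'
#' One population per incubation day. Per-cell 13C fractions at day t are
#' drawn around `f_mean(t)` (see [kinetics_params()]) with sd
#' `heterogeneity_sd0 * heterogeneity_decay^(t - 1)`, clipped to
#' \[0, f_max\]; day 0 cells are exactly unlabeled.
#'
#' @param days Numeric vector of incubation days (non-empty).
#' @param n_per_day Cells measured per day (default 45, a realistic
#'   single-cell Raman acquisition batch).
#' @param kinetics A [kinetics_params()].
#' @param model,sim,seed See [simulate_population()].
#' @return Named list (one entry per day, name = day) of cell lists; each
#'   cell's `meta$day` records its timepoint.
#' @export
simulate_timecourse <- function(days = 0:5, n_per_day = 45,
                                kinetics = kinetics_params(),
                                model = default_band_model(),
                                sim = spectrum_sim_params(), seed = NULL) {
  if (length(days) == 0) stop("`days` must be non-empty")
  stopifnot(inherits(kinetics, "kinetics_params"))
  seeds <- derive_seeds(seed, length(days))
  out <- lapply(seq_along(days), function(i) {
    t <- days[i]
    mu <- f_mean(kinetics, t)
    sd_t <- kinetics$heterogeneity_sd0 * kinetics$heterogeneity_decay^(t - 1)
    f_dist <- if (t == 0) 0 else function(n)
      pmin(kinetics$f_max, pmax(0, stats::rnorm(n, mu, sd_t)))
    pop <- simulate_population(
      n_cells = n_per_day, carotenoid_fraction = 1,
      labeled_fraction = if (t == 0) 0 else 1, f_dist = f_dist,
      model = model, sim = sim, seed = seeds[[i]],
      id_prefix = sprintf("day%g_cell", t))
    lapply(pop, function(s) { s$meta$day <- t; s })
  })
  names(out) <- as.character(days)
  out
}
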