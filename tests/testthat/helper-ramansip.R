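# Shared fixtures and independent oracles for the test suite.

# Noise-free simulation settings: flat zero baseline, no spikes.
clean_sim <- function(...) {
  spectrum_sim_params(snr = Inf, baseline_coeffs = 0, spike_rate = 0, ...)
}

# A pure Lorentzian spectrum on the default grid (no baseline, no noise).
pure_lorentzian <- function(center = 1522, fwhm = 12, amplitude = 1,
                            grid = 600:1800) {
  spectrum(grid, amplitude / (1 + ((grid - center) / (fwhm / 2))^2),
           cell_id = "pure")
}

# Brute-force band-center oracle: exhaustive search over a dense grid of
# (center, width) candidates, solving amplitude and offset by linear least
# squares at each candidate. Independent of the nonlinear fitting path.
oracle_center <- function(s, window, center_step = 0.05,
                          widths = seq(8, 16, by = 1)) {
  w <- window_of_test(s, window[1], window[2])
  x <- w$wavenumber
  y <- w$intensity
  best <- c(rss = Inf, center = NA)
  for (ctr in seq(window[1], window[2], by = center_step)) {
    for (fw in widths) {
      basis <- 1 / (1 + ((x - ctr) / (fw / 2))^2)
      fit <- stats::lm.fit(cbind(basis, 1), y)
      rss <- sum(fit$residuals^2)
      if (rss < best["rss"]) best <- c(rss = rss, center = ctr)
    }
  }
  unname(best["center"])
}

window_of_test <- function(s, lo, hi) {
  i <- which(s$wavenumber >= lo & s$wavenumber <= hi & !is.na(s$intensity))
  list(wavenumber = s$wavenumber[i], intensity = s$intensity[i])
}

# Analytic integral of a Lorentzian A / (1 + ((x - c) / (w/2))^2) over
# [lo, hi]: A * (w/2) * (atan(2(hi-c)/w) - atan(2(lo-c)/w)).
lorentzian_integral <- function(lo, hi, center, fwhm, amplitude = 1) {
  g <- fwhm / 2
  amplitude * g * (atan((hi - center) / g) - atan((lo - center) / g))
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Random contig set drawn uniformly over A/C/G/T, independent of the
# package's Markov generator.
random_contigs <- function(n, len, seed, prefix = "rnd") {
  set.seed(seed)
  contig_set(data.frame(
    contig_id = sprintf("%s_%d", prefix, seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))))
}
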