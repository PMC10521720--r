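test_that("carotenoid detection separates signal from noise-only cells", {
  s <- preprocess_spectrum(simulate_spectrum(f = 0, seed = 1))
  expect_true(detect_carotenoid(s)$carotenoid)
  # fully labeled cells stay inside the search windows (1502 in [1490,1540])
  s1 <- preprocess_spectrum(simulate_spectrum(f = 1, seed = 2))
  expect_true(detect_carotenoid(s1)$carotenoid)
  zm <- band_model(within(as.data.frame(default_band_model()),
                          amplitude <- 0))
  for (seed in c(3, 14, 25, 60)) {
    nc <- preprocess_spectrum(simulate_spectrum(model = zm, seed = seed))
    expect_false(detect_carotenoid(nc)$carotenoid)
  }
  short <- spectrum(600:1000, rep(1, 401))
  expect_error(detect_carotenoid(short), "noise reference")
})

test_that("band-center estimation is exact on a noiseless Lorentzian", {
  fit <- estimate_band_center(pure_lorentzian(center = 1522), c(1490, 1540))
  expect_true(fit$ok)
  expect_lt(abs(fit$center - 1522), 0.1)
  expect_lt(abs(fit$fwhm - 12), 0.5)
})

test_that("flat noise yields ok = FALSE, not a spurious center", {
  noise <- spectrum(600:1800, with_seed_test(8, rnorm(1201, 0, 1)))
  fit <- estimate_band_center(noise, c(1490, 1540))
  expect_false(fit$ok)
  expect_true(is.na(fit$center))
})

test_that("center estimation matches the dense-grid oracle and the truth", {
  model <- default_band_model()
  err <- vapply(1:100, function(seed) {
    s <- preprocess_spectrum(simulate_spectrum(f = 0.5, seed = seed))
    estimate_band_center(s, c(1490, 1540))$center - 1512
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.2)  # bias
  expect_lt(sd(err), 1)           # spread at snr 20
  for (seed in c(7, 31, 54)) {
    s <- preprocess_spectrum(simulate_spectrum(f = 0.5, seed = seed))
    impl <- estimate_band_center(s, c(1490, 1540))$center
    oracle <- oracle_center(s, c(1490, 1540))
    expect_lt(abs(impl - oracle), 0.2)
  }
})

test_that("shifts reproduce the printed day-1 arithmetic", {
  ref <- list(v1 = 1522, v2 = 1158)
  s <- preprocess_spectrum(simulate_spectrum(f = 0.5, seed = 7))
  fits <- list(v1 = list(center = 1512, ok = TRUE),
               v2 = list(center = 1151, ok = TRUE))
  sh <- compute_shift(s, ref, fits = fits)
  expect_equal(sh$v1_shift, 10)
  expect_equal(sh$v2_shift, 7)
  same <- compute_shift(s, ref, fits = list(v1 = list(center = 1522, ok = TRUE),
                                            v2 = list(center = 1158, ok = TRUE)))
  expect_equal(same$v1_shift, 0)
  expect_equal(same$v2_shift, 0)
})

test_that("the nu1 intensity ratio matches its analytic value and is monotone", {
  # noiseless fully labeled cell: ratio equals the analytic Lorentzian
  # window-integral ratio
  s <- simulate_spectrum(f = 1, sim = clean_sim())
  sh <- compute_shift(s, list(v1 = 1522, v2 = 1158))
  a13 <- lorentzian_integral(1496, 1508, 1502, 12)
  a12 <- lorentzian_integral(1516, 1528, 1502, 12)
  expect_equal(sh$v1_ratio, a13 / (a12 + a13), tolerance = 0.01)
  expect_gt(sh$v1_ratio, 0.85)

  ratios <- vapply(seq(0, 1, by = 0.1), function(f) {
    s <- simulate_spectrum(f = f, sim = clean_sim())
    compute_shift(s, list(v1 = 1522, v2 = 1158))$v1_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios >= 0 & ratios <= 1))
})

test_that("shifts are invariant to intensity rescaling and smooth baselines", {
  raw <- simulate_spectrum(f = 0.5, sim = spectrum_sim_params(snr = 50,
                                                              spike_rate = 0),
                           seed = 9)
  ref <- list(v1 = 1522, v2 = 1158)
  base <- compute_shift(preprocess_spectrum(raw), ref)
  scaled <- raw; scaled$intensity <- raw$intensity * 7
  sh_scaled <- compute_shift(preprocess_spectrum(scaled), ref)
  expect_equal(sh_scaled$v1_shift, base$v1_shift, tolerance = 0.1)
  expect_equal(sh_scaled$v1_ratio, base$v1_ratio, tolerance = 0.02)
  ramped <- raw
  ramped$intensity <- raw$intensity + 0.001 * (raw$wavenumber - 600) + 0.3
  sh_ramp <- compute_shift(preprocess_spectrum(ramped), ref)
  expect_equal(sh_ramp$v1_shift, base$v1_shift, tolerance = 0.2)
})

test_that("average_spectrum pools cells channel-wise, ignoring missing", {
  g <- 600:1800
  a <- spectrum(g, rep(2, 1201), "a")
  b <- spectrum(g, rep(2, 1201), "b")
  avg <- average_spectrum(list(a, b))
  expect_equal(avg$mean$intensity, rep(2, 1201))
  expect_equal(avg$sd, rep(0, 1201))

  up <- spectrum(g, rep(3, 1201), "up"); dn <- spectrum(g, rep(1, 1201), "dn")
  expect_equal(average_spectrum(list(up, dn))$mean$intensity, rep(2, 1201))

  holey <- spectrum(g, c(NA, rep(2, 1200)), "h")
  avg <- average_spectrum(list(a, holey))
  expect_equal(avg$n[1], 1)
  expect_equal(avg$mean$intensity[1], 2)

  cells <- preprocess_cells(simulate_population(45, labeled_fraction = 0,
                                                seed = 1))
  m <- average_spectrum(cells)$mean
  w <- window_of_test(m, 1490, 1540)
  expect_lt(abs(w$wavenumber[which.max(w$intensity)] - 1522), 1)
  expect_error(average_spectrum(list(a, spectrum(g + 0.5, rep(1, 1201)))),
               "common grid")
})

test_that("shift histograms use left-closed right-open bins", {
  h <- shift_histogram(rep(0, 12), bin_width = 2)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_lo, 0)
  expect_equal(h$count, 12L)
  h <- shift_histogram(c(10, 10, 7), bin_width = 2)
  expect_equal(h$count[h$bin_lo == 10], 2L)
  expect_equal(h$count[h$bin_lo == 6], 1L)
  expect_equal(sum(h$count), 3L)
  # boundary value falls in the right-open upper bin
  h <- shift_histogram(c(2), bin_width = 2)
  expect_equal(h$bin_lo, 2)
})

test_that("day-1 shift dispersion exceeds the post-steady-state dispersion", {
  tc <- simulate_timecourse(days = c(1, 3), n_per_day = 20, seed = 2)
  tc <- lapply(tc, preprocess_cells)
  ref <- list(v1 = 1522, v2 = 1158)
  sds <- vapply(tc, function(cells) {
    tab <- analyze_bands(cells, reference = ref)
    sd(tab$v1_shift[tab$carotenoid])
  }, numeric(1))
  expect_gt(sds[["1"]], sds[["3"]])
})
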