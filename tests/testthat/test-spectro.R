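test_that("a pure tone concentrates energy at its frequency in every frame", {
  fs <- 22050
  t <- seq(0, 0.2, by = 1 / fs)
  s <- compute_spectrogram(sin(2 * pi * 3000 * t), fs)
  expect_equal(nrow(s$magnitudes), 256 / 2 + 1)
  peak_freq <- apply(s$magnitudes, 2, function(col) {
    spec_freqs(s)[which.max(col)]
  })
  expect_true(all(abs(peak_freq - 3000) <= s$freq_bin_hz))
})

test_that("an all-zero waveform gives all-zero magnitudes", {
  s <- compute_spectrogram(numeric(1000), 22050, normalize = FALSE)
  expect_true(all(s$magnitudes == 0))
})

test_that("spectrogram geometry follows the configured step", {
  fs <- 22050
  s <- compute_spectrogram(rnorm(5000), fs, fft_size = 256,
                           time_step_s = 0.003)
  expect_equal(s$time_step_s, round(0.003 * fs) / fs)
  expect_true(all(s$magnitudes >= 0))
})

test_that("degenerate waveforms are refused", {
  expect_error(compute_spectrogram(numeric(100), 22050), "too short")
  expect_error(compute_spectrogram(c(rnorm(500), NA), 22050), "non-finite")
  expect_error(compute_spectrogram(rnorm(500), 22050, time_step_s = 1e-9),
               "shorter than one sample")
})

test_that("a rising chirp has a nondecreasing ridge matching a direct DFT", {
  fs <- 22050
  t <- seq(0, 0.3, by = 1 / fs)
  w <- sin(2 * pi * (2000 * t + 0.5 * (4000 - 2000) / 0.3 * t^2))
  s <- compute_spectrogram(w, fs)
  ridge <- apply(s$magnitudes, 2, function(col) spec_freqs(s)[which.max(col)])
  # monotone up to one-bin quantisation wobble
  expect_true(all(diff(ridge) >= -s$freq_bin_hz))
  oracle <- dft_ridge(w, fs)
  expect_equal(ridge, oracle, tolerance = 1e-8)
})

test_that("band limiting keeps exactly the bins whose centres fall in band", {
  s <- compute_spectrogram(rnorm(3000), 22050)
  full <- band_limit(s, 0, 22050 / 2)
  expect_identical(full$magnitudes, s$magnitudes)

  bl <- band_limit(s, 2000, 4000)
  centers <- (0:(nrow(s$magnitudes) - 1)) * s$freq_bin_hz
  expect_equal(nrow(bl$magnitudes), sum(centers >= 2000 & centers <= 4000))
  expect_true(all(spec_freqs(bl) >= 2000 & spec_freqs(bl) <= 4000))

  expect_error(band_limit(s, 3000, 3000), "f_lo_hz < f_hi_hz")
  expect_error(band_limit(s, -1, 4000), "f_lo_hz")
})

test_that("self-correlation is 1 at lag 0 and shift recovers the lag", {
  set.seed(1)
  call <- gen_contact_call(call_template(cbind(c(0, 1), c(2500, 3500)), 0.15))
  s <- spec_of(call)
  self <- xcorr_score(s, s)
  expect_equal(self$value, 1, tolerance = 1e-9)
  expect_equal(self$best_lag_frames, 0L)

  k <- 5L
  shifted <- s
  shifted$magnitudes <- cbind(matrix(0, nrow(s$magnitudes), k), s$magnitudes)
  sc <- xcorr_score(s, shifted)
  expect_equal(sc$value, 1, tolerance = 1e-6)
  expect_equal(sc$best_lag_frames, -k)
})

test_that("both engines match a brute-force lag search on varied pairs", {
  set.seed(7)
  cfg <- spectro_config()
  for (i in 1:6) {
    a <- spec_of(gen_contact_call(.random_template_test()), cfg)
    b <- spec_of(gen_contact_call(.random_template_test()), cfg)
    n_short <- min(ncol(a$magnitudes), ncol(b$magnitudes))
    min_ov <- max(1L, as.integer(ceiling(0.75 * n_short)))
    oracle <- brute_xcorr(a$magnitudes, b$magnitudes, n_short, min_ov)
    for (eng in c("cpp", "r")) {
      sc <- xcorr_score(a, b, engine = eng)
      expect_equal(sc$value, oracle$value, tolerance = 1e-9)
      expect_equal(sc$best_lag_frames, oracle$lag)
      expect_equal(sc$overlap_frames, oracle$overlap)
    }
  }
})

test_that("scores are symmetric, bounded, and amplitude invariant", {
  set.seed(2)
  cfg <- spectro_config()
  for (i in 1:4) {
    ca <- gen_contact_call(.random_template_test())
    cb <- gen_contact_call(.random_template_test())
    a <- spec_of(ca, cfg); b <- spec_of(cb, cfg)
    ab <- xcorr_score(a, b); ba <- xcorr_score(b, a)
    expect_equal(ab$value, ba$value, tolerance = 1e-9)
    expect_equal(ab$best_lag_frames, -ba$best_lag_frames)
    expect_true(abs(ab$value) <= 1)

    ca_scaled <- list(waveform = 0.037 * ca$waveform,
                      sample_rate_hz = ca$sample_rate_hz)
    a2 <- band_limit(
      compute_spectrogram(ca_scaled$waveform, ca$sample_rate_hz,
                          normalize = FALSE),
      cfg$band_lo_hz, cfg$band_hi_hz)
    a1 <- band_limit(
      compute_spectrogram(ca$waveform, ca$sample_rate_hz, normalize = FALSE),
      cfg$band_lo_hz, cfg$band_hi_hz)
    expect_equal(xcorr_score(a1, b)$value, xcorr_score(a2, b)$value,
                 tolerance = 1e-9)
  }
})

test_that("zero-variance overlaps are flagged undefined, not scored 0", {
  z <- compute_spectrogram(numeric(2000), 22050, normalize = FALSE)
  sc <- xcorr_score(z, z)
  expect_true(sc$undefined)
  expect_true(is.na(sc$value))
})

test_that("incompatible geometry and impossible overlap are errors", {
  s1 <- compute_spectrogram(rnorm(2000), 22050)
  s2 <- compute_spectrogram(rnorm(2000), 44100)
  expect_error(xcorr_score(s1, s2), "incompatible")
  s3 <- band_limit(s1, 1000, 6000)
  expect_error(xcorr_score(s1, s3), "incompatible")
  expect_error(xcorr_score(s1, s1, min_overlap_frac = 2), "overlap")
})

test_that("independent noise spectrograms score near zero", {
  set.seed(3)
  vals <- replicate(30, {
    a <- compute_spectrogram(rnorm(22050 * 0.3), 22050)
    b <- compute_spectrogram(rnorm(22050 * 0.3), 22050)
    xcorr_score(a, b)$value
  })
  # the maximum over ~50 admissible lags of correlations whose null sd is
  # 1/sqrt(overlap_cells) ~ 0.01: small and positively biased
  expect_true(all(abs(vals) < 0.2))
  expect_gt(mean(vals), 0)
  expect_lt(mean(vals), 0.1)
})
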