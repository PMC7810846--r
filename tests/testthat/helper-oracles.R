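# Independent oracles used across the suite.

# Brute-force best-lag Pearson search: double loop over lags, correlation
# via stats::cor on the flattened overlap.  Deliberately naive and
# independent of the package's prefix-sum/FFT implementations.
brute_xcorr <- function(A, B, max_lag, min_overlap) {
  best <- -Inf; best_lag <- NA_integer_; best_ov <- NA_integer_
  lag_order <- unique(as.integer(unlist(lapply(0:max_lag, function(l) c(l, -l)))))
  for (L in lag_order) {
    ia0 <- max(1L, 1L + L); ia1 <- min(ncol(A), ncol(B) + L)
    ov <- ia1 - ia0 + 1L
    if (ov < min_overlap) next
    xa <- as.vector(A[, ia0:ia1]); xb <- as.vector(B[, (ia0 - L):(ia1 - L)])
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
    r <- stats::cor(xa, xb)
    if (r > best) { best <- r; best_lag <- L; best_ov <- ov }
  }
  list(value = best, lag = best_lag, overlap = best_ov)
}

# spectrogram from a waveform under a config (public path)
spec_of <- function(call, config = spectro_config()) {
  band_limit(
    compute_spectrogram(call$waveform, call$sample_rate_hz,
                        fft_size = config$fft_size,
                        time_step_s = config$time_step_ms / 1000,
                        window = config$window),
    config$band_lo_hz, min(config$band_hi_hz, call$sample_rate_hz / 2))
}

# per-frame ridge frequencies by direct DFT of the raw windowed frames,
# independent of compute_spectrogram's mvfft route
dft_ridge <- function(waveform, fs, fft_size = 256, hop = 66) {
  starts <- seq(1, length(waveform) - fft_size + 1, by = hop)
  k <- 0:(fft_size / 2)
  vapply(starts, function(s) {
    x <- waveform[s:(s + fft_size - 1)]
    mags <- vapply(k, function(kk) {
      Mod(sum(x * exp(-2i * pi * kk * (0:(fft_size - 1)) / fft_size)))
    }, numeric(1))
    (which.max(mags) - 1) * fs / fft_size
  }, numeric(1))
}

# small balanced two-way ANOVA by explicit balanced-design sums of squares
balanced_two_way_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y) / (nlevels(a) * nlevels(b))
  gm <- mean(y)
  ssa <- nlevels(b) * n * sum((tapply(y, a, mean) - gm)^2)
  ssb <- nlevels(a) * n * sum((tapply(y, b, mean) - gm)^2)
  cell <- tapply(y, interaction(a, b), mean)
  ssc <- n * sum((cell - gm)^2)
  ssab <- ssc - ssa - ssb
  sse <- sum((y - ave(y, interaction(a, b)))^2)
  dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1
  dfab <- dfa * dfb; dfe <- length(y) - nlevels(a) * nlevels(b)
  list(FA = (ssa / dfa) / (sse / dfe), FB = (ssb / dfb) / (sse / dfe),
       FAB = (ssab / dfab) / (sse / dfe), dfe = dfe)
}

# a template drawn from the generator's type model
.random_template_test <- function() pairvox:::.random_template()
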