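#' Short-time Fourier spectrogram of a call waveform
#'
#' Computes a linear-magnitude sonogram with the geometry used throughout
#' the similarity pipeline: an FFT of `fft_size` samples per frame and a
#' fixed frame step of `time_step_s` seconds (defaults 256 samples / 3 ms,
#' the standard settings for budgerigar contact-call sonograms).
#'
#' @param waveform Numeric vector of sampled amplitudes (mono).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param fft_size FFT window length in samples.
#' @param time_step_s Frame step in seconds; the hop is
#'   `round(time_step_s * sample_rate_hz)` samples and must be >= 1.
#' @param window Analysis window: `"hamming"` (default), `"hann"`,
#'   `"blackman"` or `"rectangular"`.
#' @param normalize If `TRUE`, the waveform is peak-normalised before the
#'   transform.  Cross-correlation scores are amplitude-invariant either
#'   way; normalisation only stabilises the stored magnitudes.
#' @return A `spectrogram` object: list with `magnitudes`
#'   (`fft_size/2 + 1` frequency rows x time-frame columns, linear
#'   magnitude), `freq_bin_hz`, `bin_offset` (index of the first retained
#'   bin, 0 = DC), `time_step_s`, `fft_size`, `sample_rate_hz`,
#'   `window_name`.
#' @export
compute_spectrogram <- function(waveform, sample_rate_hz,
                                fft_size = 256, time_step_s = 0.003,
                                window = "hamming", normalize = TRUE) {
  if (!is.numeric(waveform)) stop("waveform must be numeric")
  if (any(!is.finite(waveform))) stop("waveform contains non-finite samples")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (length(waveform) < fft_size) {
    stop(sprintf("waveform too short: %d samples < one %d-sample window",
                 length(waveform), fft_size))
  }
  hop <- round(time_step_s * sample_rate_hz)
  if (hop < 1) stop("time_step_s shorter than one sample")

  if (normalize) {
    peak <- max(abs(waveform))
    if (peak > 0) waveform <- waveform / peak
  }
  w <- .stft_window(window, fft_size)
  starts <- seq(1, length(waveform) - fft_size + 1, by = hop)
  frames <- vapply(starts,
                   function(s) waveform[s:(s + fft_size - 1)] * w,
                   numeric(fft_size))
  spec <- stats::mvfft(frames)
  mags <- Mod(spec[seq_len(fft_size / 2 + 1), , drop = FALSE])

  structure(
    list(magnitudes = mags,
         freq_bin_hz = sample_rate_hz / fft_size,
         bin_offset = 0L,
         time_step_s = hop / sample_rate_hz,
         fft_size = as.integer(fft_size),
         sample_rate_hz = sample_rate_hz,
         window_name = window),
    class = "spectrogram")
}

.stft_window <- function(name, n) {
  k <- seq_len(n) - 1L
  switch(name,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         blackman = 0.42 - 0.5 * cos(2 * pi * k / (n - 1)) +
           0.08 * cos(4 * pi * k / (n - 1)),
         rectangular = rep(1, n),
         stop("unknown window: ", name))
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d bins x %d frames | %.1f Hz/bin (offset %d), %.3f ms/frame, %s window\n",
    nrow(x$magnitudes), ncol(x$magnitudes), x$freq_bin_hz, x$bin_offset,
    1000 * x$time_step_s, x$window_name))
  invisible(x)
}

#' Frequency bin centres of a spectrogram
#'
#' @param spec A `spectrogram`.
#' @return Numeric vector of bin-centre frequencies in Hz, one per row.
#' @export
spec_freqs <- function(spec) {
  (spec$bin_offset + seq_len(nrow(spec$magnitudes)) - 1) * spec$freq_bin_hz
}

#' Restrict a spectrogram to a frequency band
#'
#' Keeps the rows whose bin centres lie in the closed interval
#' `[f_lo_hz, f_hi_hz]` and updates the band metadata.
#'
#' @param spec A `spectrogram`.
#' @param f_lo_hz,f_hi_hz Band edges in Hz; `0 <= f_lo_hz < f_hi_hz <=`
#'   Nyquist.
#' @return The band-limited `spectrogram`.
#' @export
band_limit <- function(spec, f_lo_hz, f_hi_hz) {
  stopifnot(inherits(spec, "spectrogram"))
  nyquist <- spec$sample_rate_hz / 2
  if (f_lo_hz < 0 || f_hi_hz > nyquist || f_lo_hz >= f_hi_hz) {
    stop("need 0 <= f_lo_hz < f_hi_hz <= Nyquist")
  }
  f <- spec_freqs(spec)
  keep <- which(f >= f_lo_hz & f <= f_hi_hz)
  if (length(keep) == 0) stop("empty frequency band")
  spec$magnitudes <- spec$magnitudes[keep, , drop = FALSE]
  spec$bin_offset <- spec$bin_offset + keep[1] - 1L
  spec
}

#' Spectrogram cross-correlation score
#'
#' Slides one sonogram against the other in whole-frame steps and, at each
#' admissible lag, computes the Pearson correlation between the two
#' magnitude matrices over their overlapping columns (all frequency bins of
#' the overlap, flattened).  The returned score is the maximum over lags: 1
#' means the sonograms are identical (up to amplitude scaling), 0 means no
#' similarity, and the score is bounded in `[-1, 1]`.
#'
#' A lag is admissible when the overlap is at least
#' `max(1, ceiling(min_overlap_frac * min(n_a, n_b)))` frames and
#' `|lag| <= max_lag_frames`.  Ties on the maximum are broken toward the
#' smallest `|lag|` (positive before negative).  A lag where either
#' overlap has zero variance (e.g. silence against silence) carries no
#' defined correlation; if that happens at every admissible lag the result
#' is flagged `undefined` rather than scored 0.
#'
#' @param a,b `spectrogram` objects with identical frequency geometry
#'   (same bin width, same band).
#' @param max_lag_frames Maximum `|lag|` searched; default is the frame
#'   count of the shorter sonogram (i.e. the shorter call's duration).
#' @param min_overlap_frac Minimum overlap as a fraction of the shorter
#'   sonogram, default 0.75.  Permissive overlap minimums let a short
#'   call slide far along a longer one and correlate only a cherry-picked
#'   fragment, which inflates scores between unrelated calls; 0.75 keeps
#'   most of the shorter call engaged at every admissible lag.
#' @param engine `"cpp"` (compiled, default) or `"r"`; both implement the
#'   identical contract.
#' @return An `xcorr_score` object: list with `value`, `best_lag_frames`,
#'   `overlap_frames`, and logical `undefined`.
#' @export
xcorr_score <- function(a, b, max_lag_frames = NULL, min_overlap_frac = 0.75,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(a, "spectrogram"), inherits(b, "spectrogram"))
  if (abs(a$freq_bin_hz - b$freq_bin_hz) > 1e-9 ||
      a$bin_offset != b$bin_offset ||
      nrow(a$magnitudes) != nrow(b$magnitudes)) {
    stop("incompatible frequency geometry (bin width or band differs)")
  }
  na <- ncol(a$magnitudes)
  nb <- ncol(b$magnitudes)
  if (na == 0 || nb == 0) stop("empty spectrogram")
  n_short <- min(na, nb)
  if (is.null(max_lag_frames)) max_lag_frames <- n_short
  min_overlap <- max(1L, as.integer(ceiling(min_overlap_frac * n_short)))
  if (min_overlap > n_short) stop("no lag satisfies the overlap minimum")

  res <- if (engine == "cpp") {
    xcorr_best_lag_cpp(a$magnitudes, b$magnitudes,
                       as.integer(max_lag_frames), as.integer(min_overlap))
  } else {
    .xcorr_best_lag_r(a$magnitudes, b$magnitudes,
                      as.integer(max_lag_frames), min_overlap)
  }
  if (res[4] < 0) stop("no lag satisfies the overlap minimum")
  structure(
    list(value = if (res[4] > 0.5) NA_real_ else res[1],
         best_lag_frames = if (res[4] > 0.5) NA_integer_ else as.integer(res[2]),
         overlap_frames = if (res[4] > 0.5) NA_integer_ else as.integer(res[3]),
         undefined = res[4] > 0.5),
    class = "xcorr_score")
}

#' @export
print.xcorr_score <- function(x, ...) {
  if (x$undefined) {
    cat("<xcorr_score> undefined (zero-variance overlap at every lag)\n")
  } else {
    cat(sprintf("<xcorr_score> value %.4f at lag %+d (overlap %d frames)\n",
                x$value, x$best_lag_frames, x$overlap_frames))
  }
  invisible(x)
}

# Pure-R engine.  Lag L aligns column t of `a` with column t - L of `b`
# (positive lag: b shifted later).  Lags are visited in order of
# increasing |L|, positive first, and only a strictly greater correlation
# displaces the incumbent, which implements the tie-break.
.xcorr_best_lag_r <- function(A, B, max_lag, min_overlap) {
  na <- ncol(A); nb <- ncol(B); f <- nrow(A)
  lag_order <- unique(as.integer(
    unlist(lapply(0:max_lag, function(l) c(l, -l)))))
  best <- -Inf; best_lag <- NA_integer_; best_ov <- NA_integer_
  any_admissible <- FALSE
  for (L in lag_order) {
    ia0 <- max(1L, 1L + L); ia1 <- min(na, nb + L)
    ov <- ia1 - ia0 + 1L
    if (ov < min_overlap) next
    any_admissible <- TRUE
    xa <- A[, ia0:ia1, drop = FALSE]
    xb <- B[, (ia0 - L):(ia1 - L), drop = FALSE]
    n <- ov * f
    sa <- sum(xa); sb <- sum(xb)
    va <- sum(xa * xa) - sa * sa / n
    vb <- sum(xb * xb) - sb * sb / n
    if (va <= 0 || vb <= 0) next
    r <- (sum(xa * xb) - sa * sb / n) / sqrt(va * vb)
    if (r > best) {
      best <- r; best_lag <- L; best_ov <- ov
    }
  }
  if (!any_admissible) return(c(NA_real_, NA_real_, NA_real_, -1))
  if (!is.finite(best)) return(c(NA_real_, NA_real_, NA_real_, 1))
  c(min(1, max(-1, best)), best_lag, best_ov, 0)
}
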