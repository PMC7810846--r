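#' Template for a frequency-modulated contact call
#'
#' A call type is described by a smooth frequency contour (control points
#' interpolated by a cubic spline), a duration, and a small harmonic stack.
#' Exemplars generated from one template share the contour but carry
#' per-call jitter, mimicking the within-type variation of natural contact
#' calls.
#'
#' @param contour Two-column matrix or data.frame: column 1 is time as a
#'   fraction of the call in `[0, 1]` (strictly increasing), column 2 the
#'   fundamental frequency in Hz (positive).  At least 2 points.
#' @param duration_s Call duration in seconds (> 0).
#' @param n_harmonics Number of harmonics including the fundamental.
#' @param harmonic_decay Amplitude ratio between successive harmonics.
#' @param snr_db Signal-to-noise ratio of additive white noise in dB;
#'   `-Inf` is the noise-only sentinel (no tonal component).
#' @return A `call_template` object.
#' @export
call_template <- function(contour, duration_s, n_harmonics = 2,
                          harmonic_decay = 0.45, snr_db = 25) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 2 || ncol(contour) != 2) {
    stop("contour needs >= 2 rows of (time fraction, frequency Hz)")
  }
  if (is.unsorted(contour[, 1], strictly = TRUE)) {
    stop("contour time fractions must be strictly increasing")
  }
  if (any(contour[, 2] <= 0)) stop("contour frequencies must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  structure(
    list(contour = unname(contour), duration_s = duration_s,
         n_harmonics = as.integer(n_harmonics),
         harmonic_decay = harmonic_decay, snr_db = snr_db),
    class = "call_template")
}

#' Synthesise one contact-call exemplar from a template
#'
#' Renders the template's contour as a tonal FM sweep with its harmonic
#' stack and additive white noise, plus small per-call jitter (a global
#' frequency offset, control-point perturbations and a duration scaling)
#' so repeated exemplars of a type are similar but not identical.  Jitter
#' draws come from the current RNG state; seed upstream for determinism.
#'
#' @param template A [call_template()].
#' @param sample_rate_hz Output sampling rate.
#' @param freq_jitter_hz SD of the per-call global frequency offset.
#' @param contour_jitter_hz SD of independent per-control-point frequency
#'   perturbations.
#' @param time_jitter SD of the multiplicative duration jitter.
#' @param edge_s Raised-cosine onset/offset ramp in seconds.
#' @return List with `waveform` (peak-normalised to 0.9) and
#'   `sample_rate_hz`.
#' @export
gen_contact_call <- function(template, sample_rate_hz = 22050,
                             freq_jitter_hz = 40, contour_jitter_hz = 50,
                             time_jitter = 0.03, edge_s = 0.008) {
  stopifnot(inherits(template, "call_template"))
  nyquist <- sample_rate_hz / 2
  if (any(template$contour[, 2] >= nyquist)) {
    stop("contour exceeds the Nyquist frequency")
  }

  dur <- template$duration_s * max(0.5, 1 + stats::rnorm(1, 0, time_jitter))
  n <- max(2L, round(dur * sample_rate_hz))

  noise_only <- is.infinite(template$snr_db) && template$snr_db < 0
  if (noise_only) {
    w <- stats::rnorm(n, 0, 0.1)
    w <- w / max(abs(w)) * 0.9
    return(list(waveform = w, sample_rate_hz = sample_rate_hz))
  }

  ctr <- template$contour
  f_pts <- ctr[, 2] + stats::rnorm(1, 0, freq_jitter_hz) +
    stats::rnorm(nrow(ctr), 0, contour_jitter_hz)
  f_pts <- pmin(pmax(f_pts, 100), nyquist * 0.98)
  f <- stats::spline(ctr[, 1], f_pts, xout = seq(0, 1, length.out = n),
                     method = "natural")$y
  f <- pmin(pmax(f, 100), nyquist * 0.98)

  phase <- 2 * pi * cumsum(f) / sample_rate_hz
  sig <- numeric(n)
  for (h in seq_len(template$n_harmonics)) {
    if (max(f) * h >= nyquist) break
    sig <- sig + template$harmonic_decay^(h - 1) * sin(h * phase)
  }

  ne <- min(n %/% 2, max(2L, round(edge_s * sample_rate_hz)))
  env <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = ne))
  env[seq_len(ne)] <- ramp
  env[(n - ne + 1):n] <- rev(ramp)
  sig <- sig * env

  p_sig <- mean(sig^2)
  noise_sd <- sqrt(p_sig / 10^(template$snr_db / 10))
  w <- sig + stats::rnorm(n, 0, noise_sd)
  w <- w / max(abs(w)) * 0.9
  list(waveform = w, sample_rate_hz = sample_rate_hz)
}

#' Distort a call template to model imperfect imitation
#'
#' Returns a copy of the template whose contour frequencies are displaced
#' by random amounts with expected absolute displacement
#' `d * max_contour_shift_hz` (half-normal perturbation law), and whose
#' duration is rescaled by a factor drawn uniformly within
#' `d * max_duration_scale` of 1.  `d = 0` reproduces the template
#' exactly; `d = 1` is the configured maximum distortion.
#'
#' @param template A [call_template()].
#' @param d Distortion in `[0, 1]`.
#' @param max_contour_shift_hz Expected absolute contour displacement at
#'   `d = 1`, in Hz.
#' @param max_duration_scale Half-width of the duration scaling at `d = 1`.
#' @return A distorted `call_template`.
#' @export
gen_imitation <- function(template, d, max_contour_shift_hz = 300,
                          max_duration_scale = 0.15) {
  stopifnot(inherits(template, "call_template"))
  if (d < 0 || d > 1) stop("d must lie in [0, 1]")
  if (d == 0) return(template)
  ctr <- template$contour
  # half-normal: E|N(0, s)| = s * sqrt(2/pi), so s = target * sqrt(pi/2)
  s <- d * max_contour_shift_hz * sqrt(pi / 2)
  ctr[, 2] <- pmax(300, ctr[, 2] + stats::rnorm(nrow(ctr), 0, s))
  dur <- template$duration_s *
    (1 + stats::runif(1, -d * max_duration_scale, d * max_duration_scale))
  call_template(ctr, dur, template$n_harmonics, template$harmonic_decay,
                template$snr_db)
}

# root-mean-square frequency distance between two template contours on
# the shared control-point grid
.tpl_dist <- function(t1, t2) {
  sqrt(mean((t1$contour[, 2] - t2$contour[, 2])^2))
}

# draw a template at least min_dist_hz away from every template in
# `others` (rejection sampling; falls back to the farthest candidate)
.distinct_template <- function(others, min_dist_hz, tries = 100) {
  best <- NULL
  best_d <- -Inf
  for (i in seq_len(tries)) {
    cand <- .random_template()
    d <- if (length(others) == 0) Inf
         else min(vapply(others, .tpl_dist, numeric(1), t1 = cand))
    if (d >= min_dist_hz) return(cand)
    if (d > best_d) { best <- cand; best_d <- d }
  }
  best
}

# A new call type is a perturbation of a species-typical FM contour:
# contact calls of one species share a general rise-fall structure, and
# the per-type spread (SD per control point) sets how far types differ.
# At 180 Hz spread, scores between exemplars of unrelated types average
# ~0.55 and within-type exemplar scores ~0.75.
.random_template <- function(type_spread_hz = 180,
                             dur_range = c(0.10, 0.25), snr_db = 25) {
  tt <- c(0, 0.25, 0.5, 0.75, 1)
  base <- c(2500, 3200, 2900, 3400, 2700)
  ff <- pmin(pmax(base + stats::rnorm(5, 0, type_spread_hz), 1800), 4500)
  call_template(cbind(tt, ff), stats::runif(1, dur_range[1], dur_range[2]),
                snr_db = snr_db)
}

#' Simulate a budgerigar colony with post-pairing vocal imitation
#'
#' Builds pre-pairing repertoires for `n_pairs` male/female pairs with
#' mutually dissimilar call types, then post-pairing male repertoires in
#' which each male has added an imitation of one of his mate's types at
#' distortion `imitation_distortion`, alongside his retained pre-pairing
#' types.  Ground truth records which female type was imitated and the
#' label of the imitated male type.
#'
#' @param n_pairs Number of male/female pairs.
#' @param imitation_distortion Distortion `d` in `[0, 1]` applied to the
#'   imitated template (0 = perfect copy).
#' @param female_types,male_types_pre Candidate counts of call types per
#'   female / per male pre-pairing; one value is sampled per bird.
#' @param exemplars_per_call_type Exemplars generated per type.
#' @param imitate If `FALSE`, males add no imitated type (null colony).
#' @param min_type_dist_hz Minimum root-mean-square contour distance kept
#'   between a bird's own types and between a male's pre-pairing types
#'   and his mate's (pairs are formed dissociatively with respect to
#'   their calls).
#' @param sample_rate_hz Sampling rate of generated audio.
#' @param seed Optional integer seed; fixing it makes the whole colony,
#'   including the annotation table, reproducible byte for byte.
#' @param write_dir Optional directory: writes per-call WAV files,
#'   `annotations.csv`, `pairs.csv` and `ground_truth.json` there.
#' @return A `colony` list: `annotations` (bird_id, sex, timepoint,
#'   call_id, type_label, wav_path), `pairs` (male_id, female_id),
#'   `waveforms` (named list of `call_id -> list(waveform,
#'   sample_rate_hz)`), `ground_truth` (per pair: imitated female type and
#'   imitated male type label, or `NA` for a null colony).
#' @export
gen_colony <- function(n_pairs = 12, imitation_distortion = 0,
                       female_types = 1:2, male_types_pre = 2:3,
                       exemplars_per_call_type = 5, imitate = TRUE,
                       min_type_dist_hz = 300, sample_rate_hz = 22050,
                       seed = NULL, write_dir = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (imitation_distortion < 0 || imitation_distortion > 1) {
    stop("imitation_distortion must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)

  ann <- list()
  waves <- list()
  gt <- list()
  pairs <- data.frame(
    male_id = sprintf("M%02d", seq_len(n_pairs)),
    female_id = sprintf("F%02d", seq_len(n_pairs)),
    stringsAsFactors = FALSE)

  add_calls <- function(bird, sex, timepoint, type_label, template, k) {
    for (i in seq_len(k)) {
      call_id <- sprintf("%s_%s_%s_c%d", bird, timepoint, type_label, i)
      waves[[call_id]] <<- gen_contact_call(template, sample_rate_hz)
      ann[[length(ann) + 1]] <<- data.frame(
        bird_id = bird, sex = sex, timepoint = timepoint,
        call_id = call_id, type_label = type_label, wav_path = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  for (p in seq_len(n_pairs)) {
    m_id <- pairs$male_id[p]
    f_id <- pairs$female_id[p]
    n_f <- if (length(female_types) > 1) sample(female_types, 1) else female_types
    n_m <- if (length(male_types_pre) > 1) sample(male_types_pre, 1) else male_types_pre

    # pair members are "paired dissociatively": a male's pre-pairing
    # types are kept distinct from his mate's (and birds' own types from
    # each other), mirroring the study design where no pair shared
    # similar calls before pairing
    f_templates <- list()
    for (j in seq_len(n_f)) {
      f_templates[[j]] <- .distinct_template(f_templates, min_type_dist_hz)
    }
    m_templates <- list()
    for (j in seq_len(n_m)) {
      m_templates[[j]] <- .distinct_template(c(f_templates, m_templates),
                                             min_type_dist_hz)
    }

    for (j in seq_len(n_f)) {
      add_calls(f_id, "female", "pre", sprintf("%s_t%d", f_id, j),
                f_templates[[j]], exemplars_per_call_type)
    }
    for (j in seq_len(n_m)) {
      add_calls(m_id, "male", "pre", sprintf("%s_t%d", m_id, j),
                m_templates[[j]], exemplars_per_call_type)
    }
    # post-pairing male repertoire: retained pre types ...
    for (j in seq_len(n_m)) {
      add_calls(m_id, "male", "post", sprintf("%s_t%d", m_id, j),
                m_templates[[j]], exemplars_per_call_type)
    }
    # ... plus one imitated mate type, unless this is a null colony
    if (imitate) {
      imit_j <- sample(n_f, 1)
      imit_label <- sprintf("%s_imit", m_id)
      imit_tpl <- gen_imitation(f_templates[[imit_j]], imitation_distortion)
      add_calls(m_id, "male", "post", imit_label, imit_tpl,
                exemplars_per_call_type)
      gt[[m_id]] <- list(female_type = sprintf("%s_t%d", f_id, imit_j),
                         male_type = imit_label,
                         distortion = imitation_distortion)
    } else {
      gt[[m_id]] <- list(female_type = NA_character_,
                         male_type = NA_character_, distortion = NA_real_)
    }
  }

  annotations <- do.call(rbind, ann)
  colony <- structure(
    list(annotations = annotations, pairs = pairs, waveforms = waves,
         ground_truth = gt, sample_rate_hz = sample_rate_hz),
    class = "colony")

  if (!is.null(write_dir)) {
    dir.create(file.path(write_dir, "wav"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in names(waves)) {
      path <- file.path(write_dir, "wav", paste0(id, ".wav"))
      write_wav(waves[[id]]$waveform, waves[[id]]$sample_rate_hz, path)
      colony$annotations$wav_path[colony$annotations$call_id == id] <- path
    }
    # the CSV carries paths relative to write_dir so that a fixed seed
    # yields a byte-identical file wherever the colony is materialised
    ann_csv <- colony$annotations
    ann_csv$wav_path <- file.path("wav", paste0(ann_csv$call_id, ".wav"))
    utils::write.csv(ann_csv, file.path(write_dir, "annotations.csv"),
                     row.names = FALSE)
    utils::write.csv(pairs, file.path(write_dir, "pairs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(gt, file.path(write_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  colony
}

#' @export
print.colony <- function(x, ...) {
  cat(sprintf("<colony> %d pairs, %d calls, %d annotation rows\n",
              nrow(x$pairs), length(x$waveforms), nrow(x$annotations)))
  invisible(x)
}
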