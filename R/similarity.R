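#' Spectrogram settings for the similarity pipeline
#'
#' Bundles the analysis parameters handed to [compute_spectrogram()],
#' [band_limit()] and [xcorr_score()] by the repertoire-level functions.
#'
#' @param fft_size FFT window length (samples).
#' @param time_step_ms Frame step in milliseconds.
#' @param window STFT window name.
#' @param band_lo_hz,band_hi_hz Analysis band in Hz; rows outside it are
#'   dropped before correlation.
#' @param min_overlap_frac Minimum overlap fraction of the shorter call.
#' @param max_lag_frames Lag search limit; `NULL` = the shorter call's
#'   length.
#' @param resample_to Common sampling rate to which mismatched inputs are
#'   resampled (linear interpolation); `NULL` refuses mismatched rates.
#' @return A `spectro_config` list.
#' @export
spectro_config <- function(fft_size = 256, time_step_ms = 3,
                           window = "hamming", band_lo_hz = 1000,
                           band_hi_hz = 6000, min_overlap_frac = 0.75,
                           max_lag_frames = NULL, resample_to = NULL) {
  structure(
    list(fft_size = fft_size, time_step_ms = time_step_ms, window = window,
         band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
         min_overlap_frac = min_overlap_frac, max_lag_frames = max_lag_frames,
         resample_to = resample_to),
    class = "spectro_config")
}

# waveform list -> band-limited spectrogram under a spectro_config
.call_spectrogram <- function(call, config, target_rate = NULL) {
  sr <- call$sample_rate_hz
  w <- call$waveform
  if (!is.null(target_rate) && sr != target_rate) {
    if (is.null(config$resample_to)) {
      stop("sampling rates differ and resampling is disabled ",
           "(set resample_to in spectro_config)")
    }
    n_out <- round(length(w) * target_rate / sr)
    w <- stats::approx(seq_along(w), w, n = n_out)$y
    sr <- target_rate
  }
  s <- compute_spectrogram(w, sr, fft_size = config$fft_size,
                           time_step_s = config$time_step_ms / 1000,
                           window = config$window)
  band_limit(s, config$band_lo_hz, min(config$band_hi_hz, sr / 2))
}

#' Randomly select call exemplars of one type
#'
#' Samples `k` distinct calls uniformly without replacement; if fewer than
#' `k` exist, all are returned.
#'
#' @param type_calls Vector or list of calls of one type (e.g. call ids or
#'   annotation rows).
#' @param k Number of exemplars wanted (>= 1).
#' @param seed Optional seed for reproducible selection.
#' @return `k` (or all, if fewer) elements of `type_calls`.
#' @export
select_exemplars <- function(type_calls, k = 5, seed = NULL) {
  n <- if (is.data.frame(type_calls)) nrow(type_calls) else length(type_calls)
  if (n == 0) stop("no calls of this type")
  if (k < 1) stop("k must be >= 1")
  if (n <= k) return(type_calls)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, k)
  if (is.data.frame(type_calls)) type_calls[idx, , drop = FALSE]
  else type_calls[idx]
}

#' Score every exemplar pair between two repertoires
#'
#' Compares each exemplar of each male post-pairing call type against each
#' exemplar of each female pre-pairing type by spectrogram
#' cross-correlation, returning one row per exemplar pair.  A pair whose
#' score is undefined or errors is recorded with `NA` and a note, never
#' dropped silently.
#'
#' @param male_types,female_types Named lists: `type_label -> list of
#'   calls`, each call either a `list(waveform, sample_rate_hz)` or a
#'   precomputed `spectrogram`.
#' @param config A [spectro_config()].
#' @return Data frame with columns `male_type`, `female_type`,
#'   `male_call`, `female_call` (indices or names), `xcorr`, `best_lag`,
#'   `note`.
#' @export
repertoire_scores <- function(male_types, female_types,
                              config = spectro_config()) {
  if (length(male_types) == 0 || length(female_types) == 0) {
    stop("need at least one exemplar per side")
  }
  prep <- function(types) {
    lapply(types, function(calls) lapply(calls, function(cl) {
      if (inherits(cl, "spectrogram")) cl
      else .call_spectrogram(cl, config, target_rate = config$resample_to)
    }))
  }
  ms <- prep(male_types)
  fs <- prep(female_types)

  flat <- function(types) {
    data.frame(type = rep(names(types), vapply(types, length, 1L)),
               idx = unlist(lapply(types, seq_along)),
               stringsAsFactors = FALSE)
  }
  m_tab <- flat(ms); f_tab <- flat(fs)
  m_specs <- unlist(ms, recursive = FALSE, use.names = FALSE)
  f_specs <- unlist(fs, recursive = FALSE, use.names = FALSE)

  geom <- vapply(c(m_specs, f_specs), function(s) {
    c(s$freq_bin_hz, s$bin_offset, nrow(s$magnitudes))
  }, numeric(3))
  if (any(apply(geom, 1, function(v) max(v) - min(v)) > 1e-9)) {
    stop("incompatible frequency geometry across calls (bin width or band)")
  }

  max_lag <- if (is.null(config$max_lag_frames)) -1L
             else as.integer(config$max_lag_frames)
  tab <- xcorr_table_cpp(lapply(m_specs, `[[`, "magnitudes"),
                         lapply(f_specs, `[[`, "magnitudes"),
                         max_lag, config$min_overlap_frac)
  nb <- nrow(f_tab)
  i <- rep(seq_len(nrow(m_tab)), each = nb)
  j <- rep(seq_len(nb), nrow(m_tab))
  note <- character(nrow(tab))
  note[tab[, 4] > 0.5] <- "undefined (zero-variance overlap)"
  note[tab[, 4] < -0.5] <- "no lag satisfies the overlap minimum"
  data.frame(male_type = m_tab$type[i], female_type = f_tab$type[j],
             male_call = m_tab$idx[i], female_call = f_tab$idx[j],
             xcorr = ifelse(abs(tab[, 4]) > 0.5, NA_real_, tab[, 1]),
             best_lag = ifelse(abs(tab[, 4]) > 0.5, NA_integer_,
                               as.integer(tab[, 2])),
             note = note, stringsAsFactors = FALSE)
}

#' Maximum Cross-correlation Value (MCV)
#'
#' The mean of the three highest correlation values over all exemplar
#' comparisons between two repertoires.  With fewer than three finite
#' scores the mean of what exists is returned, flagged degenerate.
#'
#' @param scores Numeric vector of cross-correlation values (NAs from
#'   undefined comparisons are ignored).
#' @return An `mcv_result`: list with `top_three` (descending), `mcv`,
#'   `n_comparisons` (finite scores used) and `degenerate`.
#' @export
max_crosscorr_value <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0) stop("no finite scores")
  top <- sort(scores, decreasing = TRUE)[seq_len(min(3, length(scores)))]
  structure(
    list(top_three = top, mcv = mean(top), n_comparisons = length(scores),
         degenerate = length(scores) < 3),
    class = "mcv_result")
}

#' @export
print.mcv_result <- function(x, ...) {
  cat(sprintf("<mcv_result> MCV %.4f over %d comparisons (top: %s)%s\n",
              x$mcv, x$n_comparisons,
              paste(sprintf("%.3f", x$top_three), collapse = ", "),
              if (x$degenerate) " [degenerate: <3 scores]" else ""))
  invisible(x)
}

# paired Wilcoxon signed-rank with the pipeline's conventions: zero
# differences dropped before ranking; if none remain, p = 1 by policy.
.paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0,
                method = "Wilcoxon signed-rank (all differences zero)"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = length(d) <= 25, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = length(d), method = wt$method)
}

#' Within-pair versus extra-pair MCV comparison
#'
#' Paired Wilcoxon signed-rank test of each male's MCV against his mate
#' versus his mean MCV against all non-mate females, with group means and
#' standard errors.
#'
#' @param mcv_within Numeric vector, one value per male.
#' @param mcv_extra Numeric vector, same males in the same order.
#' @return List with `statistic` (signed-rank V), `p_value` (two-tailed),
#'   `n`, `mean_within`, `sem_within`, `mean_extra`, `sem_extra`,
#'   `method`.
#' @export
within_vs_extra_pair <- function(mcv_within, mcv_extra) {
  res <- .paired_wilcoxon(mcv_within, mcv_extra)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  c(res[c("statistic", "p_value", "method")],
    list(n = length(mcv_within),
         mean_within = mean(mcv_within), sem_within = sem(mcv_within),
         mean_extra = mean(mcv_extra), sem_extra = sem(mcv_extra)))
}

#' Within-type versus among-type score consistency
#'
#' Mann-Whitney U test of cross-correlation values within a visually
#' classified call type against values among different types.
#'
#' @param within_type_scores,among_type_scores Numeric vectors.
#' @param alternative Passed to [stats::wilcox.test()]; default
#'   two-sided.
#' @return List with `U`, `p_value`, `n_within`, `n_among`,
#'   `mean_within`, `sem_within`, `mean_among`, `sem_among`.
#' @export
type_consistency_stats <- function(within_type_scores, among_type_scores,
                                   alternative = "two.sided") {
  if (length(within_type_scores) == 0 || length(among_type_scores) == 0) {
    stop("both samples must be non-empty")
  }
  if (length(unique(c(within_type_scores, among_type_scores))) == 1) {
    u <- length(within_type_scores) * length(among_type_scores) / 2
    return(list(U = u, p_value = 1,
                n_within = length(within_type_scores),
                n_among = length(among_type_scores),
                mean_within = mean(within_type_scores), sem_within = 0,
                mean_among = mean(among_type_scores), sem_among = 0))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(within_type_scores, among_type_scores,
                       alternative = alternative))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_within = length(within_type_scores),
       n_among = length(among_type_scores),
       mean_within = mean(within_type_scores),
       sem_within = sem(within_type_scores),
       mean_among = mean(among_type_scores),
       sem_among = sem(among_type_scores))
}

#' One-way ANOVA of scores across visual-rating groups, with Scheffé
#' post-hocs
#'
#' Tests whether cross-correlation values differ among the three visual
#' CC Similarity Score groups (1/2/3) and compares every pair of groups
#' with the Scheffé procedure on the pooled error term.
#'
#' @param scores Numeric cross-correlation values.
#' @param ratings Group labels (visual ratings) parallel to `scores`.
#' @return List with `anova` (an `anova_result`) and `scheffe`, a data
#'   frame of pairwise comparisons with Scheffé-adjusted p-values.
#' @export
score_group_anova <- function(scores, ratings) {
  g <- factor(ratings)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 values")
  aov_res <- one_way_anova(scores, g)

  k <- nlevels(g)
  n <- tapply(scores, g, length)
  m <- tapply(scores, g, mean)
  df2 <- aov_res$df2
  mse <- sum(tapply(scores, g, function(v) sum((v - mean(v))^2))) / df2
  combs <- utils::combn(levels(g), 2)
  scheffe <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    diff <- m[[g1]] - m[[g2]]
    t2 <- diff^2 / (mse * (1 / n[[g1]] + 1 / n[[g2]]))
    p <- stats::pf(t2 / (k - 1), k - 1, df2, lower.tail = FALSE)
    data.frame(group1 = g1, group2 = g2, diff = diff,
               p_adjusted = p, stringsAsFactors = FALSE)
  }))
  list(anova = aov_res, scheffe = scheffe)
}

#' Pre- versus post-pairing similarity score test
#'
#' Paired Wilcoxon signed-rank test of each male's CC Similarity Score
#' after pairing against the same male's score before pairing.
#'
#' @param pre_scores,post_scores Numeric vectors, one value per male.
#' @return As [within_vs_extra_pair()], with `mean_pre`/`mean_post`
#'   labels.
#' @export
prepost_score_test <- function(pre_scores, post_scores) {
  res <- .paired_wilcoxon(post_scores, pre_scores)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  c(res[c("statistic", "p_value", "method")],
    list(n = length(pre_scores),
         mean_pre = mean(pre_scores), sem_pre = sem(pre_scores),
         mean_post = mean(post_scores), sem_post = sem(post_scores)))
}

#' Kruskal-Wallis test of scores across stimulus groups
#'
#' @param scores Numeric values.
#' @param groups Group labels parallel to `scores` (>= 2 groups).
#' @return List with `H`, `df`, `p_value`, and per-group means/SEMs.
#' @export
kruskal_groups <- function(scores, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (length(unique(scores)) == 1) {
    # all observations tied: no rank variation, H = 0 by convention
    return(list(H = 0, df = nlevels(g) - 1, p_value = 1,
                group_means = tapply(scores, g, mean)))
  }
  kt <- stats::kruskal.test(scores, g)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value,
       group_means = tapply(scores, g, mean),
       group_sems = tapply(scores, g, sem))
}
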