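#' Run configuration for the analysis pipelines
#'
#' Collects every tunable of both pipeline arms with validated defaults.
#' The configuration round-trips losslessly through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param spectro A [spectro_config()].
#' @param exemplars_per_type Exemplars sampled per call type.
#' @param ieg_log_base,ieg_log_offset Log transform used on densities.
#' @param bayes_prior `"reference"` or `"normal"`.
#' @param alpha Significance level.
#' @param report_digits Rounding used in human-readable reports (machine
#'   output is never rounded).
#' @param seed Seed for exemplar selection and any other randomness.
#' @return A `run_config` list.
#' @export
run_config <- function(spectro = spectro_config(), exemplars_per_type = 5,
                       ieg_log_base = exp(1), ieg_log_offset = 1,
                       bayes_prior = "reference", alpha = 0.05,
                       report_digits = 3, seed = 1L) {
  stopifnot(inherits(spectro, "spectro_config"),
            exemplars_per_type >= 1, alpha > 0, alpha < 1,
            bayes_prior %in% c("reference", "normal"))
  structure(
    list(spectro = spectro, exemplars_per_type = exemplars_per_type,
         ieg_log_base = ieg_log_base, ieg_log_offset = ieg_log_offset,
         bayes_prior = bayes_prior, alpha = alpha,
         report_digits = report_digits, seed = as.integer(seed)),
    class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- do.call(spectro_config, y$spectro)
  y$spectro <- NULL
  do.call(run_config, c(list(spectro = sp), y))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$spectro <- unclass(y$spectro)
  yaml::write_yaml(y, path)
  invisible(path)
}

# group annotation rows of one bird/timepoint into type -> calls lists
.repertoire_of <- function(colony, bird, timepoint, k, config) {
  ann <- colony$annotations
  rows <- ann[ann$bird_id == bird & ann$timepoint == timepoint, ]
  if (nrow(rows) == 0) stop("no calls for ", bird, " at ", timepoint)
  out <- list()
  for (tl in unique(rows$type_label)) {
    ids <- rows$call_id[rows$type_label == tl]
    ids <- select_exemplars(ids, k)
    out[[tl]] <- lapply(ids, function(id) colony$waveforms[[id]])
  }
  out
}

#' Run the full vocal-imitation similarity analysis
#'
#' Scores every male post-pairing repertoire against every female
#' pre-pairing repertoire by spectrogram cross-correlation (exemplars
#' selected per type), computes the Maximum Cross-correlation Value per
#' male-female combination, and tests within-pair against extra-pair
#' MCVs with a paired Wilcoxon signed-rank test.  The male type achieving
#' the top score against the mate is reported per pair (the inferred
#' imitated type).
#'
#' @param colony A `colony` from [gen_colony()], or an equivalent list
#'   with `annotations`, `pairs`, `waveforms` (annotations may carry
#'   `wav_path` instead of in-memory waveforms).
#' @param config A [run_config()].
#' @param out_dir Optional output directory; writes `scores.csv`,
#'   `mcv.csv` and `stats.json`.
#' @return List with `scores` (per exemplar pair), `mcv` (per
#'   male x female: relation, MCV, top male type), `stats`
#'   (within-vs-extra Wilcoxon and summary means).
#' @export
run_similarity <- function(colony, config = run_config(), out_dir = NULL) {
  if (is.null(colony$annotations) || nrow(colony$annotations) == 0) {
    stop("empty annotations")
  }
  if (is.null(colony$waveforms) || length(colony$waveforms) == 0) {
    if (!"wav_path" %in% names(colony$annotations) ||
        anyNA(colony$annotations$wav_path)) {
      stop("no waveforms and no wav_path column")
    }
    colony$waveforms <- lapply(
      stats::setNames(colony$annotations$wav_path,
                      colony$annotations$call_id),
      function(p) {
        w <- read_wav(p)
        list(waveform = w$waveform, sample_rate_hz = w$sample_rate_hz)
      })
  }
  set.seed(config$seed)
  pairs <- colony$pairs
  males <- pairs$male_id
  females <- pairs$female_id
  k <- config$exemplars_per_type

  m_reps <- lapply(stats::setNames(males, males), function(m) {
    .repertoire_of(colony, m, "post", k, config)
  })
  f_reps <- lapply(stats::setNames(females, females), function(f) {
    .repertoire_of(colony, f, "pre", k, config)
  })
  # precompute spectrograms once per call
  spectrify <- function(reps) {
    lapply(reps, function(types) lapply(types, function(calls) {
      lapply(calls, .call_spectrogram, config = config$spectro,
             target_rate = config$spectro$resample_to)
    }))
  }
  m_specs <- spectrify(m_reps)
  f_specs <- spectrify(f_reps)

  score_rows <- list()
  mcv_rows <- list()
  for (m in males) {
    mate <- pairs$female_id[pairs$male_id == m]
    for (f in females) {
      sc <- repertoire_scores(m_specs[[m]], f_specs[[f]],
                              config = config$spectro)
      sc <- cbind(data.frame(male_id = m, female_id = f,
                             relation = if (f == mate) "within_pair"
                                        else "extra_pair",
                             stringsAsFactors = FALSE),
                  sc)
      score_rows[[length(score_rows) + 1]] <- sc
      mv <- max_crosscorr_value(sc$xcorr)
      # the inferred imitated type: the male type whose best
      # per-(male type, female type) top-3 mean is highest (the MCV
      # statistic at type level; more stable than the single best score,
      # which rides the tail of hundreds of comparisons)
      top3 <- function(v) {
        v <- v[is.finite(v)]
        if (length(v) == 0) return(NA_real_)
        mean(sort(v, decreasing = TRUE)[seq_len(min(3, length(v)))])
      }
      per_pairtype <- stats::aggregate(
        xcorr ~ male_type + female_type, sc, top3, na.action = stats::na.pass)
      per_type <- tapply(per_pairtype$xcorr, per_pairtype$male_type, max)
      top_type <- names(per_type)[which.max(per_type)]
      mcv_rows[[length(mcv_rows) + 1]] <- data.frame(
        male_id = m, female_id = f, relation = sc$relation[1],
        mcv = mv$mcv, top1 = mv$top_three[1],
        top2 = if (length(mv$top_three) > 1) mv$top_three[2] else NA_real_,
        top3 = if (length(mv$top_three) > 2) mv$top_three[3] else NA_real_,
        n_comparisons = mv$n_comparisons, degenerate = mv$degenerate,
        top_male_type = top_type, max_score = max(sc$xcorr, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, score_rows)
  mcv <- do.call(rbind, mcv_rows)

  within <- mcv$mcv[mcv$relation == "within_pair"][match(males,
    mcv$male_id[mcv$relation == "within_pair"])]
  extra <- vapply(males, function(m) {
    mean(mcv$mcv[mcv$male_id == m & mcv$relation == "extra_pair"])
  }, numeric(1))
  stats_out <- list(
    within_vs_extra = if (length(males) >= 2 && any(is.finite(extra))) {
      within_vs_extra_pair(within, unname(extra))
    } else NULL,
    n_pairs = length(males))

  out <- list(scores = scores, mcv = mcv, stats = stats_out)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(mcv, file.path(out_dir, "mcv.csv"), row.names = FALSE)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  out
}

#' Run the full IEG expression analysis
#'
#' For each IEG: a two-way ANOVA (Stimulus x Brain Region) on
#' log-transformed densities, one-way ANOVAs per region with Bonferroni
#' post-hocs, per-group pairwise inter-region Pearson correlations and
#' Bayesian simple regressions with the credible-interval zero criterion,
#' and scaled rank-concordance expression profiles.  Groups with fewer
#' than 3 birds have correlations skipped with an explicit notice;
#' zero-variance comparisons are flagged undefined, never scored 0.  The
#' report is invariant to the row order of the input table.
#'
#' @param counts Count table data frame (see [density_from_counts()]) or
#'   a CSV path.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; writes `ieg_report.json`, a
#'   tidy `ieg_tests.csv` and a human-readable `summary.txt`.
#' @return Nested list report; see Details in the vignette.
#' @export
run_ieg <- function(counts, config = run_config(), out_dir = NULL) {
  if (is.character(counts)) counts <- utils::read.csv(counts)
  counts <- counts[do.call(order, counts[c("ieg", "group", "region",
                                           "bird_id")]), ]
  dens <- density_from_counts(counts)
  lg <- function(x) log_transform(x, base = config$ieg_log_base,
                                  offset = config$ieg_log_offset)
  corr_regions <- intersect(c("CMM", "dNCM", "vNCM"), unique(dens$region))

  report <- list()
  tidy <- list()
  for (ieg in sort(unique(dens$ieg))) {
    d <- dens[dens$ieg == ieg, ]
    y <- lg(d$density_per_mm2)
    r_ieg <- list()

    # two-way Stimulus x Brain Region (balanced designs only)
    r_ieg$two_way <- tryCatch(
      two_way_anova(y, d$group, d$region),
      error = function(e) list(note = conditionMessage(e)))
    if (!is.null(r_ieg$two_way$A)) {
      r_ieg$two_way$A$effect <- "Stimulus"
      r_ieg$two_way$B$effect <- "BrainRegion"
      r_ieg$two_way$interaction$effect <- "Stimulus:BrainRegion"
      for (eff in r_ieg$two_way) {
        tidy[[length(tidy) + 1]] <- data.frame(
          ieg = ieg, test = "two_way_anova", term = eff$effect,
          statistic = eff$F, df1 = eff$df1, df2 = eff$df2, p = eff$p,
          stringsAsFactors = FALSE)
      }
    }

    # one-way per region + Bonferroni post-hocs
    r_ieg$one_way <- list()
    for (reg in sort(unique(d$region))) {
      dr <- d[d$region == reg, ]
      ar <- one_way_anova(lg(dr$density_per_mm2), dr$group)
      ph <- bonferroni_posthoc(lg(dr$density_per_mm2), dr$group)
      r_ieg$one_way[[reg]] <- list(anova = ar, posthoc = ph)
      tidy[[length(tidy) + 1]] <- data.frame(
        ieg = ieg, test = "one_way_anova", term = reg, statistic = ar$F,
        df1 = ar$df1, df2 = ar$df2, p = ar$p, stringsAsFactors = FALSE)
    }

    # per-group correlation structure + Bayesian fits + pattern profiles
    r_ieg$groups <- list()
    for (g in sort(unique(d$group))) {
      dg <- d[d$group == g & d$region %in% corr_regions, ]
      n_birds <- length(unique(dg$bird_id))
      entry <- list()
      if (n_birds < 3) {
        entry$note <- sprintf(
          "group %s has %d birds (< 3): correlations skipped", g, n_birds)
      } else {
        entry$correlations <- region_correlation_matrix(dg, corr_regions)
        mat <- lg(.region_matrix(dg, corr_regions))
        prs <- utils::combn(corr_regions, 2)
        entry$bayes <- list()
        for (i in seq_len(ncol(prs))) {
          nm <- paste(prs[1, i], prs[2, i], sep = "-")
          entry$bayes[[nm]] <- if (stats::sd(mat[, prs[1, i]]) == 0) {
            list(note = "predictor constant: regression undefined")
          } else {
            bayes_simple_regression(mat[, prs[1, i]], mat[, prs[2, i]],
                                    prior = config$bayes_prior)
          }
          cr <- entry$correlations[[nm]]
          tidy[[length(tidy) + 1]] <- data.frame(
            ieg = ieg, test = "pearson", term = paste(g, nm),
            statistic = if (cr$undefined) NA_real_ else cr$r,
            df1 = cr$n - 2, df2 = NA_integer_,
            p = if (cr$undefined) NA_real_ else cr$p,
            stringsAsFactors = FALSE)
        }
        entry$pattern <- pattern_profiles(dg, corr_regions)
      }
      r_ieg$groups[[g]] <- entry
    }
    report[[ieg]] <- r_ieg
  }
  tidy <- do.call(rbind, tidy)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "ieg_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    utils::write.csv(tidy, file.path(out_dir, "ieg_tests.csv"),
                     row.names = FALSE)
    writeLines(.ieg_summary_text(report, config$report_digits),
               file.path(out_dir, "summary.txt"))
  }
  list(report = report, tests = tidy)
}

.ieg_summary_text <- function(report, digits = 3) {
  rnd <- function(x) formatC(round(x, digits), format = "fg")
  lines <- character()
  for (ieg in names(report)) {
    lines <- c(lines, sprintf("== %s ==", ieg))
    tw <- report[[ieg]]$two_way
    if (!is.null(tw$A)) {
      for (eff in tw) {
        lines <- c(lines, sprintf("  %s: F(%d,%d) = %s, p = %s",
                                  eff$effect, eff$df1, eff$df2,
                                  rnd(eff$F), rnd(eff$p)))
      }
    }
    for (reg in names(report[[ieg]]$one_way)) {
      a <- report[[ieg]]$one_way[[reg]]$anova
      lines <- c(lines, sprintf("  %s one-way: F(%d,%d) = %s, p = %s",
                                reg, a$df1, a$df2, rnd(a$F), rnd(a$p)))
    }
    for (g in names(report[[ieg]]$groups)) {
      gr <- report[[ieg]]$groups[[g]]
      if (!is.null(gr$note)) {
        lines <- c(lines, sprintf("  %s: %s", g, gr$note))
        next
      }
      for (nm in names(gr$correlations)) {
        cr <- gr$correlations[[nm]]
        bf <- gr$bayes[[nm]]
        if (cr$undefined) {
          lines <- c(lines, sprintf("  %s %s: r undefined (zero variance)",
                                    g, nm))
        } else {
          iz <- if (!is.null(bf$includes_zero)) {
            if (bf$includes_zero) "CI includes zero" else "CI excludes zero"
          } else "regression undefined"
          lines <- c(lines, sprintf("  %s %s: r = %s, p = %s; %s",
                                    g, nm, rnd(cr$r), rnd(cr$p), iz))
        }
      }
      lines <- c(lines, sprintf("  %s rank concordance: %s (W = %s)",
                                g, report[[ieg]]$groups[[g]]$pattern$concordant,
                                rnd(report[[ieg]]$groups[[g]]$pattern$kendalls_w)))
    }
  }
  lines
}
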