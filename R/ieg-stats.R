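#' @keywords internal
# Fixed counting-frame area: 290 x 450 micrometre frames.
FRAME_AREA_MM2 <- 0.290 * 0.450

#' Convert counting-frame cell counts to densities per mm^2
#'
#' Averages the (up to four) counting-frame counts of each
#' bird x group x region x IEG cell and divides by the fixed frame area
#' of 0.290 mm x 0.450 mm = 0.1305 mm^2.  Cells with fewer than the
#' expected number of frames are averaged over the frames present, with a
#' warning; a cell with no usable frame is an error.
#'
#' @param table Data frame with columns `bird_id`, `group`, `region`,
#'   `ieg`, `frame_index`, and either `count` (nonnegative) or a
#'   precomputed `density_per_mm2` (returned as-is after validation).
#' @param expected_frames Expected frames per cell (default 4).
#' @return Data frame of one row per bird x group x region x IEG with
#'   `density_per_mm2` and `n_frames`.
#' @export
density_from_counts <- function(table, expected_frames = 4) {
  req <- c("bird_id", "group", "region", "ieg")
  if (!all(req %in% names(table))) {
    stop("missing columns: ", paste(setdiff(req, names(table)), collapse = ", "))
  }
  if ("density_per_mm2" %in% names(table)) {
    if (any(table$density_per_mm2 < 0, na.rm = TRUE)) {
      stop("densities must be nonnegative")
    }
    out <- table[c(req, "density_per_mm2")]
    out$n_frames <- NA_integer_
    return(out)
  }
  if (!"count" %in% names(table)) stop("need a `count` or `density_per_mm2` column")
  if (any(!is.finite(table$count)) || any(table$count < 0)) {
    stop("counts must be finite and nonnegative")
  }
  key <- interaction(table$bird_id, table$group, table$region, table$ieg,
                     drop = TRUE)
  if (any(tapply(table$count, key, length) > expected_frames)) {
    stop("more than ", expected_frames, " frames for some cell")
  }
  agg <- stats::aggregate(count ~ bird_id + group + region + ieg,
                          data = table, FUN = mean)
  nfr <- stats::aggregate(count ~ bird_id + group + region + ieg,
                          data = table, FUN = length)
  if (any(nfr$count < expected_frames)) {
    warning(sum(nfr$count < expected_frames),
            " cell(s) have fewer than ", expected_frames,
            " frames; averaged over frames present")
  }
  data.frame(agg[c("bird_id", "group", "region", "ieg")],
             density_per_mm2 = agg$count / FRAME_AREA_MM2,
             n_frames = nfr$count)
}

#' Log transform for density data
#'
#' Monotone `log(x + offset)` transform applied before the parametric
#' tests; the default natural `log(x + 1)` maps 0 to 0, so zero densities
#' (which occur for Fos in the vNCM under silence) stay defined.
#'
#' @param x Nonnegative numeric.
#' @param base Logarithm base (default `e`).
#' @param offset Added before the log (default 1).
#' @return Transformed values.
#' @export
log_transform <- function(x, base = exp(1), offset = 1) {
  if (any(x < 0, na.rm = TRUE)) stop("negative input to log_transform")
  log(x + offset, base = base)
}

#' Upper-tail probability of the F distribution
#'
#' `P(F_{df1, df2} > F)`, the p-value attached to an ANOVA F statistic.
#' For `df1 = 2` this equals the closed form
#' `(df2 / (df2 + 2F))^(df2/2)`.
#'
#' @param f Observed F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Upper-tail probability in `[0, 1]`.
#' @export
f_survival <- function(f, df1, df2) {
  if (any(f < 0)) stop("F must be nonnegative")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

.anova_result <- function(effect, f, df1, df2, p) {
  structure(list(effect = effect, F = f, df1 = df1, df2 = df2, p = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova> %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$effect, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' Between-groups F test with degrees of freedom `(k - 1, N - k)`.  A
#' response with zero total variance is reported as `F = 0, p = 1`.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with >= 2 values).
#' @return An `anova_result` with fields `effect`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 values")
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  if (stats::var(values) == 0) {
    return(.anova_result("group", 0, df1, df2, 1))
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  .anova_result("group", tab[1, "F value"], df1, df2,
                f_survival(tab[1, "F value"], df1, df2))
}

#' Two-way fixed-effects ANOVA with interaction (balanced designs)
#'
#' Fully crossed `A * B` fixed-effects ANOVA for the balanced case, where
#' Type-I and Type-III sums of squares coincide.  Unbalanced or
#' incomplete designs are refused.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Crossed factors.
#' @return List of three `anova_result`s: `A`, `B`, `interaction`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  cells <- table(a, b)
  if (any(cells == 0)) stop("empty cells: the design must be fully crossed")
  if (length(unique(as.vector(cells))) != 1) {
    stop("unbalanced design not supported")
  }
  fit <- stats::aov(values ~ a * b)
  tab <- summary(fit)[[1]]
  dfe <- tab[nrow(tab), "Df"]
  get <- function(row, effect) {
    f <- tab[row, "F value"]
    .anova_result(effect, f, tab[row, "Df"], dfe,
                  f_survival(f, tab[row, "Df"], dfe))
  }
  list(A = get(1, "A"), B = get(2, "B"), interaction = get(3, "A:B"))
}

#' Bonferroni-adjusted pairwise comparisons after a one-way ANOVA
#'
#' Pairwise two-sample t tests on the pooled ANOVA error term, with p
#' multiplied by the number of comparisons performed (capped at 1).
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param pairs Optional list of 2-vectors of group labels; default all
#'   pairs.
#' @return Data frame with `group1`, `group2`, `diff`, `t`, `p_raw`,
#'   `p_adjusted`.
#' @export
bonferroni_posthoc <- function(values, groups, pairs = NULL) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  lev <- levels(g)
  if (is.null(pairs)) {
    cmb <- utils::combn(lev, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  bad <- unlist(pairs)[!unlist(pairs) %in% lev]
  if (length(bad)) stop("unknown group(s): ", paste(unique(bad), collapse = ", "))

  n <- tapply(values, g, length)
  m <- tapply(values, g, mean)
  dfe <- length(values) - nlevels(g)
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / dfe
  n_comp <- length(pairs)
  do.call(rbind, lapply(pairs, function(pr) {
    d <- m[[pr[1]]] - m[[pr[2]]]
    se <- sqrt(mse * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    tval <- if (se == 0) 0 else d / se
    p_raw <- if (se == 0) 1 else 2 * stats::pt(-abs(tval), dfe)
    data.frame(group1 = pr[1], group2 = pr[2], diff = d, t = tval,
               p_raw = p_raw, p_adjusted = min(1, n_comp * p_raw),
               stringsAsFactors = FALSE)
  }))
}

#' Pearson product-moment correlation with small-n exactness
#'
#' Computes `r` and the two-tailed p from the t transform
#' `t = r sqrt(n-2) / sqrt(1-r^2)` with `n - 2` degrees of freedom.  At
#' `n = 4` this reduces exactly to `p = 1 - |r|`.  Zero variance in
#' either variable makes the correlation undefined: the result carries an
#' `undefined` flag and no numeric `r` or `p`, never a 0.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return A `correlation_result`: list with `r`, `n`, `p`, `undefined`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, n = n, p = NA_real_,
                          undefined = TRUE), class = "correlation_result"))
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tval), n - 2)
  }
  structure(list(r = r, n = n, p = p, undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$undefined) cat("<correlation> undefined (zero variance), n =", x$n, "\n")
  else cat(sprintf("<correlation> r = %.3f, n = %d, p = %.3f\n", x$r, x$n, x$p))
  invisible(x)
}

#' Pairwise inter-region correlations of per-bird densities
#'
#' Pearson correlations of (optionally log-transformed) per-bird
#' densities between the three caudomedial pallium subregions, for one
#' stimulus group and one IEG.
#'
#' @param densities Data frame with `bird_id`, `region`,
#'   `density_per_mm2` for a single group x IEG; the same birds must be
#'   present in each of CMM, dNCM and vNCM.
#' @param regions The three region labels, default
#'   `c("CMM", "dNCM", "vNCM")`.
#' @param log If `TRUE` (default) apply [log_transform()] first.
#' @return Named list of `correlation_result`s, one per region pair
#'   (`"CMM-dNCM"`, `"CMM-vNCM"`, `"dNCM-vNCM"`).
#' @export
region_correlation_matrix <- function(densities,
                                      regions = c("CMM", "dNCM", "vNCM"),
                                      log = TRUE) {
  mat <- .region_matrix(densities, regions)
  if (log) mat <- log_transform(mat)
  prs <- utils::combn(regions, 2)
  out <- list()
  for (i in seq_len(ncol(prs))) {
    r1 <- prs[1, i]; r2 <- prs[2, i]
    out[[paste(r1, r2, sep = "-")]] <- pearson_corr(mat[, r1], mat[, r2])
  }
  out
}

# densities long -> birds x regions matrix, validating completeness
.region_matrix <- function(densities, regions) {
  densities <- densities[densities$region %in% regions, ]
  birds <- sort(unique(densities$bird_id))
  mat <- matrix(NA_real_, length(birds), length(regions),
                dimnames = list(birds, regions))
  for (k in seq_len(nrow(densities))) {
    mat[as.character(densities$bird_id[k]),
        as.character(densities$region[k])] <- densities$density_per_mm2[k]
  }
  if (any(is.na(mat))) stop("some bird is missing a region")
  mat
}

#' Bayesian simple linear regression with a credible-interval zero
#' criterion
#'
#' Fits `y = alpha + beta x + e` and reports the posterior mean of the
#' slope with its 95% credible interval and an `includes_zero` flag (the
#' criterion for declaring no linear relationship).  Under the default
#' reference prior (flat on the coefficients, scale-invariant on the
#' noise) the slope posterior is a location-scale t with `n - 2` degrees
#' of freedom, so the credible interval coincides exactly with the
#' classical OLS t interval.  The optional `"normal"` prior is a
#' conjugate normal-inverse-gamma shrinkage prior with slope prior
#' `N(0, sigma^2 tau^2)`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`; `x` non-constant.
#' @param prior `"reference"` (default) or `"normal"`.
#' @param tau2 Prior slope variance scale for the `"normal"` prior.
#' @param intercept_var Prior intercept variance scale for the
#'   `"normal"` prior (vague by default).
#' @param a0,b0 Inverse-gamma noise hyperparameters for the `"normal"`
#'   prior.
#' @param level Credible level, default 0.95.
#' @return A `bayes_regression_result`: list with `slope_mean`,
#'   `ci_lo`, `ci_hi`, `includes_zero`, `prior`, `degenerate` (zero
#'   residual variance yields a point interval, flagged).
#' @export
bayes_simple_regression <- function(x, y, prior = c("reference", "normal"),
                                    tau2 = 1, intercept_var = 1e6,
                                    a0 = 0.01, b0 = 0.01, level = 0.95) {
  prior <- match.arg(prior)
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("x is constant")
  alpha2 <- (1 - level) / 2

  if (prior == "reference") {
    sxx <- sum((x - mean(x))^2)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - beta * mean(x)
    rss <- sum((y - a - beta * x)^2)
    df <- n - 2
    if (rss <= 1e-12 * max(1, sum(y^2))) {
      res <- list(slope_mean = beta, ci_lo = beta, ci_hi = beta,
                  includes_zero = beta == 0, prior = prior,
                  degenerate = TRUE)
      return(structure(res, class = "bayes_regression_result"))
    }
    se <- sqrt(rss / df / sxx)
    q <- stats::qt(1 - alpha2, df)
    lo <- beta - q * se; hi <- beta + q * se
    res <- list(slope_mean = beta, ci_lo = lo, ci_hi = hi,
                includes_zero = lo <= 0 && 0 <= hi, prior = prior,
                degenerate = FALSE)
    return(structure(res, class = "bayes_regression_result"))
  }

  # conjugate normal-inverse-gamma posterior
  X <- cbind(1, x)
  v0_inv <- diag(c(1 / intercept_var, 1 / tau2))
  vn_inv <- v0_inv + crossprod(X)
  vn <- solve(vn_inv)
  mn <- vn %*% crossprod(X, y)
  an <- a0 + n / 2
  bn <- b0 + (sum(y^2) - t(mn) %*% vn_inv %*% mn)[1] / 2
  bn <- max(bn, 1e-300)
  scale <- sqrt(bn / an * vn[2, 2])
  df <- 2 * an
  q <- stats::qt(1 - alpha2, df)
  lo <- mn[2] - q * scale; hi <- mn[2] + q * scale
  structure(
    list(slope_mean = mn[2], ci_lo = lo, ci_hi = hi,
         includes_zero = lo <= 0 && 0 <= hi, prior = prior,
         degenerate = FALSE),
    class = "bayes_regression_result")
}

#' @export
print.bayes_regression_result <- function(x, ...) {
  cat(sprintf(
    "<bayes regression> slope %.4f, 95%% CI [%.4f, %.4f]%s (%s prior)\n",
    x$slope_mean, x$ci_lo, x$ci_hi,
    if (x$includes_zero) " [includes zero]" else " [excludes zero]",
    x$prior))
  invisible(x)
}

#' Scaled expression profiles and rank concordance across subregions
#'
#' Within one stimulus group and IEG, scales each subregion's per-bird
#' densities to the bird with the highest expression in that subregion
#' (so each subregion's maximum bird maps to 100%), ranks birds within
#' each subregion (1 = highest, midranks on ties), and reports whether
#' the rank order of birds is identical across all subregions together
#' with Kendall's coefficient of concordance W.
#'
#' @param densities Data frame with `bird_id`, `region`,
#'   `density_per_mm2` for one group x IEG; >= 2 birds, all three
#'   subregions present per bird.
#' @param regions Subregion labels, default `c("CMM", "dNCM", "vNCM")`.
#' @return A `pattern_profile`: list with `scaled_percent` (birds x
#'   regions, max 100 per column), `ranks` (birds x regions, 1 =
#'   highest), `concordant`, `kendalls_w`.
#' @export
pattern_profiles <- function(densities, regions = c("CMM", "dNCM", "vNCM")) {
  mat <- .region_matrix(densities, regions)
  if (nrow(mat) < 2) stop("need >= 2 birds")
  scaled <- sweep(mat, 2, apply(mat, 2, max), "/") * 100
  ranks <- apply(mat, 2, function(v) rank(-v, ties.method = "average"))
  concordant <- all(apply(ranks, 1, function(rr) length(unique(rr)) == 1))
  structure(
    list(scaled_percent = scaled, ranks = ranks, concordant = concordant,
         kendalls_w = .kendalls_w(ranks)),
    class = "pattern_profile")
}

# Kendall's W across m rankings (columns) of k subjects (rows), with the
# standard tie correction.
.kendalls_w <- function(ranks) {
  k <- nrow(ranks); m <- ncol(ranks)
  rs <- rowSums(ranks)
  s <- sum((rs - mean(rs))^2)
  tie_corr <- sum(apply(ranks, 2, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (k^3 - k) - m * tie_corr
  if (denom <= 0) return(NA_real_)
  12 * s / denom
}

#' @export
print.pattern_profile <- function(x, ...) {
  cat(sprintf("<pattern_profile> %d birds x %d regions; concordant: %s; W = %.3f\n",
              nrow(x$ranks), ncol(x$ranks), x$concordant, x$kendalls_w))
  invisible(x)
}

#' Spearman rank correlation of similarity scores against cell densities
#'
#' Spearman rho with midrank ties; the two-tailed p is an exact
#' permutation probability for `n <= 8` and the t approximation above.
#' Constant scores make the correlation undefined (flagged, not zero).
#'
#' @param scores Per-bird CC Similarity Scores (or any ordinal).
#' @param densities Per-bird densities, same order.
#' @return List with `rho`, `n`, `p`, `undefined`.
#' @export
spearman_score_vs_counts <- function(scores, densities) {
  if (length(scores) != length(densities)) stop("lengths differ")
  n <- length(scores)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(scores) == 0 || stats::sd(densities) == 0) {
    return(list(rho = NA_real_, n = n, p = NA_real_, undefined = TRUE))
  }
  rx <- rank(scores); ry <- rank(densities)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, n = n, p = p, undefined = FALSE)
}

# all permutations of 1..n as rows (n <= 8 in practice)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
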