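Package: pairvox
Title: Vocal Imitation Scoring and Immediate-Early-Gene Co-Expression
    Statistics for Budgerigar Contact Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies vocal imitation learning in budgerigar contact
    calls by spectrogram cross-correlation (Pearson correlation of
    overlapping time-frequency cells, maximised over time lag), including
    the Maximum Cross-correlation Value summary and the behavioural rank
    and ANOVA statistics built on it, and infers memory-specific
    correlated neuronal activity from immediate-early-gene (Zenk/Fos)
    cell-count tables across caudomedial pallium subregions: density
    conversion from fixed counting frames, log transforms, one- and
    two-way ANOVAs with Bonferroni post-hocs, pairwise inter-region
    Pearson correlations with exact small-n behaviour, Bayesian simple
    regression with a 95% credible-interval zero criterion, and scaled
    rank-concordance expression profiles.  Ships synthetic generators for
    frequency-modulated contact calls (imitation scenarios with
    controllable distortion) and for grouped count tables with
    group-specific inter-region correlation, so the full pipeline is
    testable without raw recordings or histology.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
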