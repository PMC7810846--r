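---
title: "Quantifying contact-call imitation and inter-region IEG coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contact-call imitation and inter-region IEG coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairvox)
```

## The problem

Male budgerigars paired with a female imitate their mate's contact call
(CC) within weeks, creating a new call type in their repertoire.  Two
questions follow.  First, can that imitation be quantified objectively
from recordings?  `pairvox` scores acoustic similarity by spectrogram
cross-correlation and summarises repertoire-to-repertoire similarity by
the *Maximum Cross-correlation Value* (MCV).  Second, does hearing the
memorised mate call engage the caudomedial pallium (CMM, dNCM, vNCM) in
a *coordinated* way?  `pairvox` takes immediate-early-gene (Zenk, Fos)
cell-count tables and asks both whether mean expression differs across
stimulus groups (ANOVA) and whether expression is *correlated between
regions across birds* (Pearson correlation and Bayesian simple
regression with a credible-interval zero criterion) — the latter being
the functional-connectivity-style signature of memory-specific
processing.

Raw recordings and histology for such studies are rarely deposited, so
the package ships two synthetic generators that emulate the statistical
structure of both data types.  Every pipeline claim is tested against
these generators with known ground truth.

## Spectrogram cross-correlation

A call waveform is transformed to a linear-magnitude sonogram with FFT
size 256 and a 3 ms frame step (the standard settings for budgerigar CC
sonograms; Hamming window by default — the window is not part of the
published convention and is configurable).  Given two sonograms $A$
(frequency × time, $n_A$ frames) and $B$ ($n_B$ frames) with identical
frequency geometry, the score at integer lag $L$ is the Pearson
correlation over all time–frequency cells of the overlapping columns,
and

$$\mathrm{xcorr}(A, B) \;=\; \max_{L \,\in\, \mathcal{L}} \;
  \mathrm{cor}\!\left(\operatorname{vec} A_{[\cdot,\,t]},\;
                      \operatorname{vec} B_{[\cdot,\,t-L]}\right),$$

where $\mathcal{L}$ is the set of admissible lags.  A score of 1 means
the sonograms are identical up to amplitude scaling (Pearson correlation
is invariant to uniform gain); 0 means no similarity; the value is
bounded in $[-1, 1]$.

Numerical contract, including the degenerate cases:

* **Admissible lags.** $|L|$ at most the shorter call's frame count,
  and the overlap must cover at least `min_overlap_frac` (default 0.75)
  of the shorter call.  The default is deliberately strict: with a
  permissive minimum (say one half), a short call can slide far along a
  longer one and correlate only a cherry-picked fragment, which inflates
  scores between unrelated calls so much that type identification from
  scores becomes unreliable (see *Calibration* below).
* **Ties.** If several lags tie on the maximum, the smallest $|L|$ wins
  (positive before negative at equal magnitude).
* **Zero variance.** A silence-against-silence overlap has no defined
  correlation.  If every admissible lag is degenerate the result is an
  explicit `undefined` flag — never a numeric 0, which would wrongly
  assert "no similarity".
* **Mismatched sampling rates** are refused unless a common resampling
  rate is configured.

Two implementations coexist: a plain R reference engine and a compiled
engine used by the batched repertoire scorer, which precomputes each
sonogram's row-wise FFT once and obtains the correlation numerator at
every lag from a single cross-spectrum (the per-lag means and variances
come from prefix sums).  The test suite requires both engines to agree
with a naive brute-force double loop to $10^{-9}$.

## From scores to imitation statistics

Five exemplars per call type are drawn uniformly without replacement
(all of them if a type has fewer than five).  Every male post-pairing
exemplar is scored against every female pre-pairing exemplar; the MCV of
a male–female combination is the mean of the three highest scores over
all those comparisons.  Each male contributes one *within-pair* MCV
(against his mate) and one *extra-pair* MCV (the mean over all non-mate
females); the two are compared by a paired Wilcoxon signed-rank test
(zero differences dropped; exact p up to n = 25).  The remaining
behavioural statistics follow the field's conventions: Mann–Whitney U
for within-type versus among-type scores, one-way ANOVA with Scheffé
post-hocs for scores grouped by the 1/2/3 visual similarity rating, and
Kruskal–Wallis across stimulus groups.  Visual ratings are inputs, never
computed; a pair's CC Similarity Score is the highest rating over its
comparisons.

The pipeline also reports, per pair, the male call type most similar to
the mate — the candidate imitated type.  It is chosen by the highest
per-(male type, female type) top-3 mean rather than the single best
score: with hundreds of exemplar comparisons per pair, a single maximum
rides the distribution's tail, while the top-3 mean within a type pair
is the same statistic as the MCV and much more stable.

## The synthetic colony

`gen_colony()` emulates the study design: each pair's pre-pairing
repertoires, then post-pairing male repertoires in which one female type
has been imitated at a controllable distortion $d \in [0, 1]$.

* **Call model.** A call type is a smooth frequency contour (cubic
  spline through five control points) rendered as an FM tone with two
  harmonics (decay 0.45), a raised-cosine envelope, and white noise at
  25 dB SNR; sampling rate 22,050 Hz; durations 0.10–0.25 s;
  fundamentals 2–4 kHz.  These are budgerigar-like magnitudes chosen
  once as generator defaults, not published values.
* **Types and jitter.** A new type perturbs a species-typical contour by
  N(0, 180 Hz) per control point; exemplars of a type add a global
  frequency offset (SD 40 Hz), control-point jitter (SD 50 Hz) and ±3%
  duration jitter.
* **Dissociative pairing.** As in the study design, pair members start
  without similar calls: male pre-pairing templates are rejection
  sampled to keep at least 300 Hz rms contour distance from the mate's
  templates (and a bird's own types from each other).
* **Imitation.** The imitated template displaces each contour point by a
  half-normal perturbation with expected magnitude
  $d \times 300\,\mathrm{Hz}$ and rescales duration by up to
  $\pm 0.15 d$; $d = 0$ is a perfect copy.  The 300 Hz maximum makes a
  fully distorted "imitation" ($d = 1$) about as far from its target as
  an unrelated type, so $d$ spans the full range from perfect copying to
  no copying.

### Calibration

Budgerigar CC work reports spectrogram cross-correlations near 0.75
between exemplars of one visually classified type and near 0.54 between
types; those two figures guided the jitter calibration.  With the
defaults above, within-type exemplar scores average ≈ 0.73–0.78.
Among-type scores average ≈ 0.40–0.45 — lower than 0.54 — and this gap
is a deliberate trade-off: among-type means near 0.54 are reachable only
by letting unrelated types sit closer together (or by the permissive
overlap rule), and both options destroy the pipeline's ability to
recover *which* type was imitated, a property we hold to a ≥ 90%
standard at $d \le 0.2$.  Under the defaults the pipeline recovers the
ground-truth imitated type in ≈ 97% of pairs at $d = 0.2$ and finds
within-pair > extra-pair MCV (Wilcoxon p < 0.05) in every 12-pair colony
replicate; at $d = 0$ every within-pair best score clears the 0.75
threshold that chance comparisons are highly unlikely to exceed.

What the generator does **not** emulate: vocal-tract resonances, warble
song, amplitude modulation patterns, recording-channel artefacts, or
observer noise in type classification.  Passing tests therefore show
that the scoring machinery behaves correctly on FM-tonal structure of
realistic scale — not that it would reproduce any particular field
recording's numbers.

## IEG quantification and inference

Counts come from fixed 290 × 450 μm counting frames, four per region per
bird (two per hemisphere, collapsed by averaging).  Cell density is the
frame-mean count divided by 0.1305 mm² exactly.  Densities are
log-transformed as $\log(x + 1)$ before parametric tests — the offset
keeps zero densities defined (Fos in the vNCM under silence is
essentially absent), and 0 maps to 0; the base is configurable.

The inference chain per IEG:

* two-way fixed-effects ANOVA (Stimulus × Brain Region, balanced
  designs; Type-I ≡ Type-III in the balanced case);
* one-way ANOVAs per region with Bonferroni post-hocs on the pooled
  error term (p × number of comparisons, capped at 1);
* per stimulus group, pairwise Pearson correlations of per-bird
  densities between CMM, dNCM and vNCM.  At the study's n = 4 the
  two-tailed p from the t transform reduces *exactly* to
  $p = 1 - |r|$, and for $F$ tests with two numerator degrees of freedom
  $p = \left(\mathrm{df}_2/(\mathrm{df}_2 + 2F)\right)^{\mathrm{df}_2/2}$;
  both identities are enforced in the tests to $10^{-12}$ and $10^{-10}$.
  Zero-variance variables yield an `undefined` flag, never $r = 0$;
* Bayesian simple regression per region pair.  Under the default
  reference prior (flat on coefficients, scale-invariant on the noise
  variance) the slope's posterior is a location-scale t with $n - 2$
  degrees of freedom, so the 95% credible interval *equals* the
  classical OLS t interval — a testable identity, enforced to
  $10^{-9}$ — and the includes-zero criterion coincides with classical
  significance at α = 0.05.  A conjugate normal–inverse-gamma shrinkage
  prior (slope ~ N(0, σ²τ²)) is provided as an alternative because the
  original analysis software and prior are unknown and a proper prior
  can flip borderline n = 4 calls; neither prior is asserted to be the
  original authors';
* scaled expression profiles: per region, each bird's density as a
  percentage of that region's maximum bird (the maximum maps to exactly
  100%), per-region bird rankings, a concordance flag (identical rank
  order across regions), and Kendall's W with midrank tie correction;
* Spearman rank correlation (exact permutation p for n ≤ 8) between CC
  Similarity Scores and densities.

## The synthetic counting experiment

`gen_ieg_counts()` draws per-bird log densities from a multivariate
normal whose CMM/dNCM/vNCM correlation is a group-specific
equicorrelation ρ (the hippocampus control is independent), exponentiates
to densities, and draws Poisson frame counts with expectation
density × 0.1305.  Bird-level variation is log-normal because densities
are positive and right-skewed (and the analysis log-transforms); SD 0.4
on the log scale and Zenk densities of a few hundred per mm² are
realistic magnitudes for IEG immunoreactivity, chosen once.  Designated
cells (by default Fos/vNCM/SILENCE) are zero-inflated.  Group mean
ordering follows the qualitative published pattern (playback elevates
Zenk in CMM/dNCM and Fos only in vNCM); the figure values are graphical
and were never treated as numbers.

`recovery_experiment()` runs the *real* analysis chain on simulated
single-group tables across a ρ grid and reports, with binomial standard
errors, the per-pair significant fraction and the fraction of replicates
in which all three credible intervals exclude zero.  At the study's
n = 4 this quantifies both type-I calibration (≈ 0.05 at ρ = 0; slightly
above nominal, ≈ 0.057, because the log of Poisson-noised densities is
only approximately normal) and how much coupling is needed before the
all-three-pairs pattern becomes detectable more often than not
(ρ ≈ 0.99).

## Problem sizes and determinism

The shipped tests and the acceptance script use 12-pair colonies with
1–2 female and 2–3 male pre-pairing types (desk-scale stand-ins for the
study's 1–5 and 5–31), 100 colony replicates for detection rates, 2,000
replicates for type-I calibration and 400–500 per ρ for power curves —
sizes chosen so the full evidence chain reruns in minutes on one core.
All randomness flows from explicit seeds; a fixed seed reproduces every
report byte for byte, including the generated annotation CSVs.

## Known limitations

* Commercial correlator software (e.g. Avisoft Correlator) does not
  publish its exact normalisation, spectral range and step conventions;
  bit-identical reproduction of scores produced by such software is not
  attempted.
* The among-type score calibration sits below the 0.54 reference value
  (see *Calibration*).
* No repeated-measures (between × within) decomposition of the
  Stimulus × IEG design is provided: with 12 subjects no standard layout
  yields the error df such analyses are sometimes quoted with, so the
  plain fixed-effects two-way ANOVA is the supported model, and
  `f_survival()` evaluates any externally supplied F/df combination.
* Counts are consumed as tables; no image processing or cell detection
  is performed, and hemispheres are collapsed by frame averaging with no
  laterality analysis.
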