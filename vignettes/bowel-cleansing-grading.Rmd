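---
title: "Grading bowel-cleansing quality in colon capsule endoscopy and measuring rater agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading bowel-cleansing quality in colon capsule endoscopy and measuring rater agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccecleanse)
```

## The problem

Colon capsule endoscopy (CCE) records tens of thousands of frames as a
swallowed camera travels through the colon. Whether the examination is usable
depends on bowel-cleansing quality: residual fluid and fecal matter hide the
mucosa and force re-examination. Human readers grade cleansing per colon
segment on the 4-point Leighton-Rex scale (poor, fair, good, excellent), which
is collapsed to a 2-point scale (poor = nonacceptable; everything else =
acceptable). The overall examination is acceptable only if *every* segment is.
These qualitative grades are subjective, and interobserver agreement between
readers — and between readers and automated scoring — is a real clinical
question.

`ccecleanse` implements an automated grading pipeline and the statistics to
compare it with human readers:

1. **frame scoring** — each pixel of a frame is labelled clean or dirty; the
   frame is reduced to its clean-pixel fraction and a continuous cleanliness
   rating;
2. **sequence grading** — the distribution of ratings over a video sequence is
   summarized by its mean, median, quartiles, and 2nd/98th percentiles, and
   each summary is floored onto the Leighton-Rex scale;
3. **colon model** — the frame stream is split into colon segments at the
   reader-reported flexure positions; reader 5-segment grades are merged to
   the 3-segment division; overall acceptability rules are applied;
4. **agreement** — algorithm and reader grades are cross-tabulated and
   compared with percent agreement, Cohen's κ (2-point scale) and weighted κ
   (4-point scale), with confidence intervals and interpretation bands;
5. **synthetic data** — a seeded generator produces frames, rating streams and
   correlated reader reports, so the full pipeline is testable without any
   raw videos.

## Pixel classification

The production-grade pixel classifiers used on real capsule video are trained
models; this package deliberately ships a transparent rule instead. A pixel is
dirty when its HSV hue lies in a configurable yellow/brown band **and** its
saturation and brightness clear minimum thresholds:

* `hue_band = c(20, 70)` degrees — fecal residue is yellow-to-brown, mucosa is
  pink/red (hue near 340–360);
* `saturation_min = 0.35` — washed-out highlights are not called dirty;
* `value_min = 0.15` — near-black shadow pixels are not called dirty.

All three are parameters of `classifier_config()`, because the rule is a
policy, not a claim about optimal segmentation. The synthetic frame generator
paints residue blobs whose hue/saturation/value sit safely inside the band and
a mucosa background safely outside it, so on generated frames the classifier
recovers the ground-truth mask pixel for pixel — which is exactly what makes
the downstream arithmetic testable.

"Cleanliness" of a frame is the clean-pixel **fraction** `clean/(clean+dirty)`,
not the literal quotient `clean/dirty`: the fraction is bounded in [0, 1],
defined when nothing is dirty, and stable under percentile summaries. The
literal quotient is available as `clean_dirty_ratio()` for anyone who wants
it.

## The continuous rating scale

The 4-point scale needs a continuous counterpart for percentile summaries to
act on. We use the affine map

\[ r(f) = 1 + 4f, \qquad f \in [0,1], \]

clamped to \([1, 5 - \varepsilon]\) so that `floor(r)` always lands in
{1, 2, 3, 4}. Grade boundaries then fall at clean fractions of 25%, 50% and
75%: a frame under one-quarter clean is poor, three-quarters or more clean is
excellent. Published work on automated CCE cleansing scores does not pin down
the internal scale of the scoring model, so this map is a declared,
config-level policy of this package, chosen for its simplicity and its exact
grade-cell midpoints (1.5, 2.5, 3.5, 4.5), which the synthetic generator
exploits (below).

## Sequence summaries and flooring

`summarize_ratings()` computes six statistics of the empirical rating
distribution: mean, median, Q1, Q3, P2, P98. Two percentile conventions are
supported:

* `"linear"` (default): linear interpolation between closest ranks —
  `stats::quantile` type 7, the common default in scientific array libraries;
* `"nearest"`: nearest-rank (type 1).

The convention is unstated in the motivating study; it only matters for short
streams, and the choice is recorded in every summary object. Each statistic is
floored to the 4-point grade (`rating_to_grade()`): exact integers map to
themselves (`floor(3.0) = 3`), values at or above 5 cannot occur by
construction, and values below 1 — possible if a user feeds raw scores from
some other model — clamp to poor with a warning rather than an error. All six
statistics are always computed; which one drives a grading decision is a
run-level choice, because comparing the thresholds *is* the analysis.

Equal frame weighting is intentional. Human readers implicitly down-weight
stretches where the capsule lingers; the automated score gives every frame the
same impact. That difference is part of what the agreement analysis measures,
so the package does not implement dwell-time reweighting.

## Colon segmentation and overall rules

Automated scoring has no localization capability, so segment boundaries come
from the reader report as frame indices (or timestamps converted via
`timestamps_to_indices()`). Intervals are half-open `[start, end)` to avoid
double-counting boundary frames. Three-segment mode splits at the hepatic and
splenic flexures (right-sided, transverse, left-sided colon); five-segment
mode additionally uses the cecum end and rectosigmoid junction. An empty
segment is a data error naming the segment — an unobserved segment cannot be
graded — and `run_study()` drops such videos from segmental comparisons (with
a logged count) while keeping them in the whole-colon comparison.

When readers grade five segments but boundaries only support three, the reader
grades are merged by pairwise minimum: right = min(cecum, right-sided),
left = min(left-sided, rectum), transverse unchanged. The reader's overall
4-point grade is taken as the minimum over segments — a declared policy chosen
for consistency: its binary collapse provably equals the
all-segments-acceptable rule (verified exhaustively over all 4^5 grade
vectors in the test suite). The algorithm's overall grade, by contrast, is
computed on the pooled stream of all colon frames, not as a minimum of
segment grades: the automated score is a property of the frame distribution,
and pooling is its natural whole-colon analogue.

## Agreement statistics

For a k×k table of paired grades with cell proportions \(p_{ij}\), row
marginals \(p_{i\cdot}\) (algorithm) and column marginals \(p_{\cdot j}\)
(reader):

\[ \kappa_w = \frac{p_{o,w} - p_{e,w}}{1 - p_{e,w}}, \qquad
   p_{o,w} = \sum_{ij} w_{ij} p_{ij}, \quad
   p_{e,w} = \sum_{ij} w_{ij} p_{i\cdot} p_{\cdot j}, \]

with identity weights for unweighted Cohen's κ and, for ordinal scales,
linear (Cicchetti–Allison, \(w_{ij} = 1 - |i-j|/(k-1)\)) or quadratic
(Fleiss–Cohen) weights. Linear is the default for the 4-point analysis — it
is also the default of the major commercial statistics packages, so results
are comparable with clinical literature — and quadratic is a flag away. The
standard error is the large-sample (Fleiss–Cohen–Everitt) estimate computed
from the same weighted machinery (identity weights reduce it to the familiar
unweighted variance), and the 95% CI is the Wald interval truncated to
[-1, 1]. A percentile bootstrap CI (`kappa_boot_ci()`, multinomial resampling
of the n pairs) is provided as a cross-check; on the reference tables it
brackets the asymptotic interval closely.

Interpretation uses the conventional bands: ≤ .20 None, .21–.39 Minimal,
.40–.59 Weak, .60–.79 Moderate, .80–.90 Strong, > .90 Almost perfect. κ is
rounded to two decimals *before* banding, which makes the bands exhaustive
(there is no value between .20 and .21 after rounding); negative values fall
in "None". Reports print κ to two decimals without a leading zero
(".10 (.05-.16)"), percentages half-up to the published precision; full
precision always stays in the machine-readable objects.

κ is undefined when the expected agreement is 1 (all mass in a single
category for both raters); the package raises a data error, and `run_study()`
records such comparisons with `kappa = NA` rather than failing the run.

## The synthetic cohort generator

The generator replaces the study's raw videos, which are not publicly
deposited. Its model, from the top down:

* each **video** draws a latent whole-colon quality grade from
  `latent_dist`;
* each of its five **segments** keeps that grade or shifts it by ±1 with
  probability `segment_drift` (clamped to 1–4) — segment qualities within one
  patient are strongly correlated in practice, and a hierarchical latent is
  both more realistic than independent per-segment draws and necessary to
  make whole-colon marginals controllable;
* segment lengths are gamma-proportional (shape 20 keeps them plausibly even
  but variable), every segment at least one frame;
* **frame ratings** are drawn from a normal distribution truncated to
  \([1, 5)\), centered at the grade-cell midpoint `latent + 0.5` with spread
  `noise` — symmetric about the midpoint so that at zero noise *every*
  summary statistic floors back to the latent grade exactly (the end-to-end
  parameter-recovery property the test suite asserts: noiseless cohort +
  identity reader confusion ⇒ κ = 1 everywhere);
* the paired **reader report** draws each segment's reported grade from the
  row of a 4×4 confusion matrix indexed by the latent grade — identity rows
  reproduce the truth, uniform rows give a reader independent of it.

Everything is a pure function of (config, seed): the same pair reproduces
byte-identical cohorts and files.

`study_preset()` is a calibrated configuration emulating the 842-video study
conditions: `latent_dist = (0.06, 0.29, 0.40, 0.25)`, `segment_drift = 0.2`,
`noise = 0.5`, and a mostly-diagonal, adjacent-spread reader confusion
matrix. The calibration was done once, by Monte-Carlo at large n against the
two published overall 2-point marginals (≈26.4% of videos reader-nonacceptable,
≈5.9% algorithm-nonacceptable under mean grading), and then frozen. The wide
gap between the two marginals is structural, not a tuning artifact: a reader
is already nonacceptable if *any* of five segments is poor, whereas the pooled
mean rating must fall below 2 — essentially the whole colon must be poor —
before the algorithm is.

What the generator does **not** emulate: capsule dwell (frames are exchangeable
within a segment), realistic endoscopic texture (frames are flat-colored blobs
on a flat background, by design classifiable without error), bidirectional
capsule motion, or missing video material. Passing tests therefore demonstrate
the correctness of the arithmetic and the rules on cleanly-specified inputs,
not classifier performance on real mucosa.

## Numerical and design choices

* Ratings live on \([1, 5)\); the clamp margin below 5 is \(10^{-6}\).
* Exact integers floor to themselves; sub-1 summaries clamp to poor with a
  warning.
* The frame generator selects exactly `round(f · n_pixels)` dirty pixels
  (ties in the blob potential broken by a seeded jitter of order 1e-9), so
  ground truth is exact, not approximate.
* Truncated-normal sampling is inverse-CDF, so `noise = 0` degenerates to the
  center exactly rather than relying on limiting behavior.
* Brightness jitter on generated frames is multiplicative, which perturbs HSV
  value only — hue and saturation, the classification-relevant channels, are
  untouched.
* Frame image input is PNG; lexicographic file order defines frame order.
* Percentages in rendered tables are rounded half-up (not banker's rounding)
  to match the conventional clinical table style.

The test suite runs the pipeline at desk scale: cohorts of tens to hundreds
of videos with 30–400 frames each, 20 replicate cohorts of 842 videos for the
marginal-calibration check, 1,000-case property sweeps for the quantile and
κ oracles, and exhaustive enumeration (4^5 grade vectors) for the merge and
overall rules. These sizes are the package's chosen trade-off between
statistical resolution and a test suite that stays fast enough to run on
every change.

## Limitations

* The pixel classifier is a transparent stand-in; nothing here reproduces the
  behavior of trained cleansing classifiers on real frames.
* The affine fraction-to-rating map is a policy. If a different monotone map
  is preferred, only `fraction_to_rating()` changes; everything downstream is
  agnostic.
* Segmental κ values from the motivating study cannot be checked numerically
  — they require the study's raw videos. The package reproduces the published
  whole-colon results exactly from the printed tables and emits the same
  report *structure* for segmental analyses on synthetic cohorts.
* Single-rater-pair agreement only: no Fleiss κ, ICC, or Krippendorff's α.
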