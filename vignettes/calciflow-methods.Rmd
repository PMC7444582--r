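---
title: "Quantifying spermathecal calcium dynamics with calciflow"
author: "calciflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spermathecal calcium dynamics with calciflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciflow)
```

## The measurement problem

During each ovulation in *C. elegans*, an oocyte enters the spermatheca,
is fertilized, and is pushed into the uterus by coordinated contraction of
the spermathecal bag and the sp-ut valve. With a genetically encoded
indicator (GCaMP) expressed in the tissue, cytosolic Ca²⁺ appears as
fluorescence in 1 frame/s time-lapse movies. Comparing genotypes requires
turning those movies into numbers: how often Ca²⁺ pulses occur, how fast
the signal rises, how long each transit phase takes, and whether embryos
actually exit. `calciflow` implements that quantification as a tested
pipeline, and pairs it with a synthetic movie generator so each stage can
be validated against known ground truth.

## Trace extraction and normalization

The raw measurement is the arithmetic mean intensity of a rectangular ROI
drawn around the spermatheca, one value per frame. Because absolute
GCaMP brightness varies with expression level and optics, traces are
reported as **F/F₀**: F₀ is the mean of the `baseline_len = 30` frames
immediately *preceding* the annotated start of oocyte entry. Two readings
of "the first 30 frames prior to ovulation" are possible — the first 30
frames of the recording, or the 30 frames before entry; we anchor the
window at entry, which is what "prior to the start of ovulation" implies
and which is robust to recordings that start long before the event. When
fewer than 30 pre-entry frames exist the window shrinks to what is
available, with a warning, rather than failing on short recordings; a
recording with *no* pre-entry frames is an error, as is a zero baseline.

Two identities pin the implementation down and are enforced by tests: the
F/F₀ trace averages exactly 1 over the baseline window, and multiplying
every pixel by a positive constant leaves F/F₀ unchanged.

Kymograms collapse each frame to one line of per-column means over the
ROI rows; stacking the lines gives a T × W image in which a
distal-to-proximal Ca²⁺ wave is a sloped streak whose slope is the
inverse wave speed. By construction the mean of each kymogram row equals
the frame's ROI mean exactly. Kymograms are computed on raw intensities by
default, with a normalized variant behind a flag, since either display is
defensible and the choice does not affect any downstream metric.

All frame indices in the interface are 0-based (frame *i* at *i·dt*
seconds) and ROI coordinates are 0-based and half-open. This keeps the
arithmetic in annotations and tests explicit, at the cost of being
unusual for R; every function that takes a frame index documents it.

## Registration

Movies of paralyzed animals still drift slightly. We register each frame
to frame 0 by exhaustive search over integer translations within
±`max_shift` pixels, scoring zero-normalized cross-correlation on the
overlap region. Integer-only translation keeps the pipeline exactly
testable: injected shifts must be recovered *exactly*, not approximately.
Candidates are scanned in order of increasing |dy| + |dx| (then
lexicographically) and a candidate must beat the incumbent by more than
1e-9 in correlation, so exact ties — including the all-constant frame —
deterministically resolve to the smallest shift. Zero-variance frames get
shift (0, 0) with a warning rather than an error. Out-of-frame pixels
after shifting are filled with the frame median, which avoids dragging
ROI means toward 0 at the edges. Sub-pixel, rotational, and deformable
registration are out of scope.

## Peak detection and pulse metrics

Traces are smoothed with a centered 5-point moving average whose window
truncates at the trace ends (so output length equals input length), then
peaks are detected with the standard settings: minimum prominence 0.1 and
minimum width 5. "Units" here are F/F₀ units for prominence and samples
for width — at 1 frame/s a sample is a second.

The detector defines a candidate as a sample strictly greater than both
neighbours, with a flat plateau counted once at its middle sample
(left-middle when even — a determinism tie-break). Each flanking base is
the minimum of the signal between the peak and the nearer of (signal end,
next sample exceeding the peak value) on that side; prominence is the
peak value minus the higher base; width is the horizontal extent, by
linear interpolation, at the height `value − prominence/2`. These are the
conventional prominence/width semantics of 1-D peak finders. The whole
detector is validated against an independent brute-force O(n²) oracle
that recomputes every candidate's prominence by exhaustive scan, on over
a hundred pseudorandom traces including plateau-bearing ones.

Per-transit metrics are computed on the *smoothed* F/F₀ trace restricted
to the transit window — entry to valve closure, or to the end of the
recording when the valve never closes (transit-bounded counting is the
default; the alternative, counting to the recording end regardless, is a
judgment call the annotation data cannot settle):

- `n_peaks`, and `peaks_per_second = n_peaks / duration` with duration =
  (valve close − entry) or (recording end − entry). Normalizing by
  transit duration is what makes rate comparisons meaningful when
  transits differ greatly in length.
- `t_max`: time from entry to the highest-valued detected peak (earliest
  wins ties).
- `t_half_max`: time from entry to the first sample of the smoothed trace
  at or above half the maximum peak value. We use half the *absolute*
  normalized value (first-crossing semantics); the alternative — halfway
  between the 1.0 baseline and the peak — is available as
  `half_max_mode = "baseline_subtracted"`. Both are defensible readings
  of "time to half max"; the absolute form is the simpler statement and
  the default.
- `deriv_variance`: the sample variance (n − 1 denominator) of successive
  differences. Flat and linearly ramping traces score 0; this is the
  statistic used to call traces "flat" when comparing conditions.

When no peak passes the filters, `t_max` and `t_half_max` are `NA` — a
flat trace has no meaningful rise time.

## Transit timing, phenotypes, populations

Four timepoints are annotated per ovulation (by eye, as in practice —
automatic event detection from pixels is a non-goal): start of oocyte
entry, distal neck closure, sp-ut valve opening, valve closure. Derived
times: entry = neck − entry start; dwell = valve open − neck close; exit =
valve close − valve open; total = valve close − entry start. Dwell may be
negative (the valve can open before the neck closes) and is reported
as-is. Whenever all four timepoints exist, entry + dwell + exit = total
identically. Annotations are stored as frame indices and scaled by `dt`,
keeping them resolution-independent.

Phenotype classification is total and deterministic over consistent
annotations, with a fixed precedence: a reflux into the gonad arm
dominates (even if the valve later opened — re-entry events make the
flags non-exclusive, and the reflux is the biologically salient failure);
then valve-opened-and-exited; then valve-opened-without-exit; else
trapped. An exit flag without a valve opening is rejected as
inconsistent.

Population assays score each spermatheca as `unoccupied`, `occupied`,
`small_piece_or_liquid`, or `emo`. Embryo fragments and fluid-filled
spermathecae are pooled into one category because the downstream
statistics always compare unoccupied against the sum of everything else.

## Group statistics

Occupancy and phenotype comparisons use the exact 2×2 test: the
hypergeometric distribution over all tables with the observed margins,
two-sided by the probability-mass rule (sum the probabilities of all
tables at most as probable as the observed, with a 1e-7 relative
tolerance for floating-point ties — the most common convention). Metric
comparisons use the one-way ANOVA omnibus F with the upper-tail F
p-value; groups that are internally constant but differ give F = ∞ with
p = 0 and a degeneracy flag, and all-identical data is an error. Both are
checked against independent references (`stats::fisher.test`,
`anova(lm(...))`, and the two-group F = t² identity) in the test suite.
Post-hoc Tukey HSD is deliberately not implemented; pairwise comparisons
against a control are exposed as pairwise exact tests or pairwise F tests
with an optional Bonferroni correction. Significance stars follow the
reporting thresholds \*\*\*\* p<0.0001, \*\*\* p<0.005, \*\* p<0.01,
\* p<0.05.

## The synthetic movie generator

The generator produces a T × X field of normalized fluorescence,

$$F(x,t) \;=\; B \;+\; \sum_i A_0\,\bigl(1 + r\,(t_i - t_{entry})\bigr)\,
g\!\left(\frac{t - t_i - x/v}{\tau}\right) \;+\; \varepsilon(t,x),$$

with unit-peak kernel $g(u) = 2^{-u^2}$ (half-maximum at $|u| = \tau$,
so τ is a half-duration in seconds), pulse onsets
$t_i = t_{entry} + D + iP$ for every $t_i$ inside the recording, bag
positions $x \in [0,1]$ tissue-lengths with distal at column 0, and
i.i.d. Gaussian noise $\varepsilon$ of standard deviation σ fixed
bit-exactly by the seed. The Gaussian kernel is the simplest smooth shape
matching the rise-peak-fall morphology of observed pulses and makes peak
locations analytic; the linear amplitude ramp is the simplest model of a
pulse train that grows in intensity until the transit ends. The valve
occupies the proximal 10% of columns (4 syncytial valve cells against 24
bag cells — an order-of-magnitude proportion) and follows one of four
regimes: a bright entry spike followed by quiet (wild-type-like),
a sustained rise held high (the regime where bag signal is lost but the
valve stays bright), suppressed baseline, or continuing the bag wave.

Orientation: the field and all kymograms run distal-left/valve-right.
Published descriptions of movie orientation are contradictory on this
point, so the package fixes one convention and states it everywhere an
orientation appears.

Seven presets ship as JSON (`wild_type`, `gsa1_kd`, `kin1_kd`, `kin2_kd`,
`gsa1_gf`, `pde6_kd`, `empty_pulsing`). Their qualitative shapes — which
regimes pulse, which are flat, which valve behaviour, which transit
phenotype — mirror the published genotype descriptions; their
*quantitative* parameters (periods, amplitudes, noise level, wave speed)
are not published numbers but fixed choices made once at realistic scale:
baseline 1.0, noise σ = 0.02 (a few percent of baseline, shot-noise
scale for widefield imaging), pulse amplitudes 0.15–0.5 F/F₀ units,
periods 30–50 s, entry at frame 30 so a full 30-frame baseline exists.
The `kin2_kd` preset pulses every P = 30 s with A0 = 0.5 and σ = 0.02 —
the calibration used throughout the recovery tests. Ground truth (pulse
onsets, event frames, phenotype label) is emitted alongside every field.

`render_movie` is the inverse of ROI extraction: field columns become
pixel-column blocks, rows are replicated over the image height, and
values map to gray levels by a recorded affine map (`gray = round(value ·
gain + offset)`). A map that would clip at the chosen bit depth is an
error naming the offending value, never a silent saturation. Exact
block-mean reproduction holds when the pixel width is a multiple of the
field's column count, which the tests and CLI use; the ROI-mean
round-trip is then accurate to half a gray level.

What the simulator deliberately omits: 2-D tissue geometry, IP₃/ER
biophysics, photobleaching, occlusion by the embryo, and non-rigid body
motion. Passing recovery tests on synthetic movies therefore shows the
*quantification* is correct under the stated dynamics model, not that
the model captures every feature of real recordings.

## Numerical choices and degenerate inputs

- Onset generation, kernel evaluation, and noise are all computed in a
  fixed order from the seed, so identical (preset, duration, seed) give
  bit-identical fields, ground truth, and rendered TIFFs; the CLI chain
  is bit-reproducible end to end.
- Peak filtering uses ≥ comparisons; a peak exactly at a threshold is
  kept. Property tests that exercise affine invariances compare
  *unfiltered* peak sets, because a width lying exactly on the threshold
  is floating-point fragile under affine changes of the trace.
- Registration correlation ties (within 1e-9) resolve to the earliest
  candidate in the |dy| + |dx|-ordered scan.
- Fisher enumeration uses `stats::dhyper`, which works in log-space
  internally, so large margins do not overflow.
- Degenerate inputs have defined behaviour throughout: empty traces,
  zero baselines, missing entry annotations, inconsistent exit flags,
  clipping intensity maps, and zero-variance frames each produce a
  specific error or warning documented on the function.

## Problem sizes used in validation

The shipped validation battery (test suite and `scripts/acceptance.R`)
uses 600 s simulated recordings at 1 frame/s with 50 spatial columns,
100-seed batches for recovery and ordering checks, 110 pseudorandom
traces of length ≤ 200 for the peak-finder oracle, 200 random 2×2 tables
for the exact-test oracle, and 36 × 52 px frames for registration — sizes
at which every property can be checked exhaustively in well under a
minute per battery on a laptop, while remaining representative of the
real data's scale (recordings of several hundred frames, shifts of a few
pixels, tables with tens of animals).

## Known limitations

- Traces are 1-D summaries; spatial submetrics (e.g. bag-only vs
  valve-only traces) require passing sub-ROIs explicitly.
- The half-max time uses the absolute-value convention by default; when
  comparing against analyses using the baseline-subtracted convention,
  set `half_max_mode` accordingly.
- Tukey HSD post-hoc p-values are not provided.
- Registration is integer-translation only and anchored to frame 0; a
  drifting recording whose first frame is atypical should be trimmed
  before registration.
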