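---
title: "Methods: locomotor fingerprinting and condition-specific peak statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locomotor fingerprinting and condition-specific peak statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finprintr)
```

## Scope and model

`finprintr` implements two analysis tracks that share a philosophy of simple,
auditable statistics over black-box modeling:

1. **Behavioral track.** Larval zebrafish in a multi-well plate are filmed on
   a light:dark cycle; the tracking rig reports, per well and frame
   transition, the number of pixels whose grey value changed beyond an
   acquisition sensitivity threshold ("delta pixels"). From this univariate
   signal we segment **bouts**, compute **nine parameters** per day and night,
   standardize each larva against its wild-type siblings into a **Z-score
   fingerprint**, summarize phenotype strength as a **Euclidean distance**,
   and compare fingerprints to each other and to a compound library by
   **Pearson correlation**, with an average-linkage clustergram under
   correlation distance.
2. **Chromatin track.** Per-peak accessibility intensities of single cells
   from two conditions are compared with **one-tailed Wilcoxon rank-sum and
   Kolmogorov–Smirnov tests** in both directions; peaks passing raw p-value
   thresholds are "condition-specific", and a **label-shuffling permutation
   null** calibrates the number of significant peaks per cell cluster. Around
   this sit deterministic conventions for bulk region classification, Tn5
   read shifting, effective-fragment filtering, RPM coverage,
   high/low-threshold condition-specific peak calls, and promoter–peak
   association.

Every stage consumes and produces plain tabular data (tibbles, wide CSV,
BED), so the whole pipeline is testable against synthetic data with known
ground truth.

## Behavioral track

### Bout segmentation and the nine parameters

A frame is *active* iff its delta-pixel value is strictly greater than the
`activity_floor` (default 0). The floor defaults to zero because the rig's
sensitivity threshold is applied at acquisition: any nonzero value already
means detected movement. Bouts are maximal runs of constant state; they tile
the epoch exactly, and bouts truncated by an epoch boundary are included
as-is (no censoring) — deterministic and simple, at the cost of a small edge
bias that is identical across groups on a shared schedule.

Per epoch we compute: mean active-bout length (s), and the mean over active
bouts of the per-bout mean, standard deviation, total, minimum and maximum of
the delta-pixel values; the number of active bouts; the percentage of time
active; and the mean inactive-bout length (s). Two reductions deserve
mention because they are conventions, not forced choices:

* **Unweighted mean across bouts** (not pooled frames) turns per-bout
  statistics into the epoch value. A pooled-frame mean would weight long
  bouts more; the per-bout mean treats each movement event as one draw from
  the larva's behavioral repertoire, which is what the fingerprint is meant
  to capture.
* **Population (n) denominator** for the per-bout standard deviation, so a
  single-frame bout contributes 0 rather than an undefined value.

Epochs with no active bout report `n_active_bouts = 0`,
`time_active_pct = 0`, and *missing* for the six active-bout statistics;
missing never becomes zero anywhere downstream, because a larva that never
moved is not a larva whose movements had zero amplitude.

Day and night values are averaged across all complete days and nights of the
recording (partial epochs at the recording edges are excluded by default;
`segment_epochs(use = "all")` keeps them, since whether they should
contribute is genuinely ambiguous and is left to the analyst). Epoch
boundaries land on the Zeitgeber clock with half-up rounding to the nearest
frame and half-open ranges, so every frame belongs to exactly one epoch.

### Fingerprints, distances, correlations

Z-scores are computed per measure against the **reference group's sample
standard deviation (denominator n − 1)**; the denominator is a choice (the
field's description does not pin it), and the sample form is the one under
which the reference group has exactly unit variance. Reference larvae are
fingerprinted too, so the reference cloud is standardized to mean 0, sd 1 by
construction and the reference mean fingerprint sits at the origin — which
is what makes the Euclidean distance interpretable as phenotype magnitude.

Design points: SEM with one member is reported missing, not 0; correlations
are pairwise-complete over shared non-missing measures with a hard
`min_overlap` floor (default 5); distances exclude missing measures and
report `n_measures` so distances over different subsets are auditable. The
canonical measure order is the nine parameters, day block then night block,
so fingerprints and libraries interoperate by name.

### Drug matching and the clustergram

Ranking a query against a library is plain Pearson correlation per condition
with ties broken by condition name. The clustergram uses **distance
`1 − r` and average linkage (UPGMA)**: correlation distance is the natural
metric for Z-profiles (scale-free, like the ranking itself) and average
linkage is the standard clustergram default. Both choices sit behind one
function so alternatives can be added without touching callers. The
agglomeration is implemented with Lance–Williams updates and a documented
deterministic tie-break (lowest original row index), making the tree
invariant to input row order — `stats::hclust` does not guarantee a specific
tie-break, and the tests compare against a brute-force agglomeration oracle.
Library rows are condition-level: a compound at two doses is two conditions,
never aggregated.

## Chromatin track

### Per-peak one-tailed tests

For each peak and each direction ("greater in A", "greater in B"):

* **Wilcoxon rank-sum**: exact tail probability for tie-free samples with
  combined n ≤ 12 (configurable), otherwise the normal approximation with
  tie correction and 0.5 continuity correction. At single-cell cluster sizes
  the approximation is the operative branch and is accurate at the 10^-3
  tails used for screening.
* **KS**: the one-sided statistic `D = sup (F_other − F_self)` evaluated at
  run ends of the pooled sorted values (correct under ties), with the
  asymptotic one-sided bound `exp(−2 D² mn/(m+n))` as p-value, clamped to
  (0, 1]. Exact small-sample KS tails are out of scope and documented as
  such; the bound is conservative, which suits a filtering step.

A peak is significant in a direction when **both** tests pass their raw
thresholds (defaults 0.001 and 0.01). "Both" is the conservative reading of
a two-test filter and is the default; `rule = "either"` is available. No
multiplicity correction is applied at this step — deliberately, because the
calibration instrument is the permutation null, not an FDR on the raw
p-values.

### Permutation null

Each of the (default) 1000 shuffles permutes the condition labels over cells
— preserving group sizes and each peak's intensity multiset — and recounts
significant peaks (both directions, deduplicated per peak). The empirical
p-value uses the **add-one estimator** `(1 + #{null ≥ obs})/(1 + B)`, which
is valid (never anti-conservative) for exchangeable nulls and bounded below
by `1/(B+1)`.

**Calibration design.** At the default thresholds a 200-peak null matrix
yields an expected significant count of roughly 0.1, so the count statistic
is almost surely 0 and its empirical p-value is degenerate at 1 — a property
of discreteness, not of any implementation. The package's calibration
experiment therefore exercises the same shuffling engine where the statistic
has spread: Wilcoxon-only at p < 0.05 (KS threshold set to 1). Under that
regime the empirical p-values over independent null datasets are
approximately uniform (10-bin chi-square GOF at the 1% level), and the
pooled one-tailed Wilcoxon rate at p < 0.001 sits inside the exact binomial
99% interval of the nominal rate. The defaults target rare discoveries,
where the add-one estimator is conservative by design.

### Deterministic genomics conventions

All intervals are **0-based half-open** (BED convention; the choice is ours
and is applied consistently, with bit-exact BED round-trips). Overlap means
at least one shared base — abutment is not overlap. Tn5 shifts are +4 bp on
plus-strand read starts and −5 bp on minus-strand read ends; a shift that
collapses a read is an error, not a silent drop. Effective fragments are
mapq ≥ 30 (as the operational meaning of "uniquely mapped") and insert
≤ 100 bp; RPM is overlap count × 10^6 / total effective fragments. A peak is
condition-specific when called at the high threshold in one condition with
no ≥ 1 bp overlap against the other condition's low-threshold call set.
Promoters are the strand-symmetric `[max(0, TSS − 1 kb), TSS + 1 kb)`
window; half-open was chosen (closed endpoints would differ by one base and
are not distinguishable from the published description), and the `tss`
column must already be strand-aware (for minus-strand genes, the 3'-most
coordinate of the annotated span). The bulk region classes are
`up` (FDR < 0.01, ratio > 1), `down` (FDR < 0.01, ratio < 1), `unaffected`
(FDR > 0.95 and 0.995 < ratio < 1.005 — the printed window is inverted as
written in the source description and is implemented the only way it is
non-empty), else `none`; the classes are disjoint by construction.

## The synthetic-data module

The simulators define the package's study conditions; they are first-class,
tested code, not fixtures.

* **Plates**: an alternating-renewal bout process — exponential bout
  durations (means per epoch type, minimum one frame), gamma per-frame
  amplitudes (shape 2) inside active bouts, exact zeros outside. This is the
  simplest generative process whose nine-parameter signature is
  controllable: amplitude factors move the five amplitude statistics,
  bout-rate factors move bout counts and time active. Baseline defaults
  (day: 2 s active / 4 s inactive bouts; night: 1.5 s / 20 s; amplitude
  scale 10) give realistic day-active, night-quiet larvae. Defaults are 1 Hz
  and 48 h — 1 Hz keeps bout statistics in seconds and tests fast; the
  25 fps acquisition rate is a config field and exercised in tests.
  Inter-larva baseline variance is not asserted (nothing pins it); the
  config knobs are the honest interface. The default group effects plant a
  daytime-only hyperactivity (amplitude ×1.5, bout rate ×1.3), the
  recovery condition for the planted-effect validation.
* **Libraries**: standard-normal Z matrices with an optional planted mimic =
  query + Gaussian noise in Z-space, so the expected mimic correlation is
  controlled in closed form.
* **Peak matrices**: negative-binomial intensities (`mu = 10`, `size = 2` by
  default; the baseline mean is a field the generative description needs
  and is chosen once as a realistic per-cluster intensity level) with a
  planted peak subset whose condition-B mean is multiplied by the effect
  size. Zero-inflation is deliberately omitted: the downstream tests are
  rank/ECDF-based and distribution-free, so NB suffices for calibration.

What passing tests on these simulators does and does not show: they validate
the *statistical machinery* — segmentation exactness, standardization
identities, ranking recovery, test calibration — under a model whose
assumptions (exponential bouts, exchangeable cells, NB intensities) real
data need not satisfy. They do not validate tracking hardware, mapping,
peak calling, or any upstream tool the pipeline consumes tables from.

## Problem sizes and numerical choices

The validation suite uses: 1000 random traces (up to 10^4 frames) for the
segmentation oracle; a 96-well, 48 h, 1 Hz plate for planted-effect
recovery; 100 seeds × 200 conditions for mimic ranking; 100 null matrices
of 200 peaks × 100 cells for test calibration, with 1000-shuffle
permutation nulls. Standardization identities are checked to 1e−12,
clustering heights to 1e−10, oracle equivalences to 1e−12 or exactly.
P-values are clamped to (0, 1]; degenerate cases (zero-variance peaks,
single-member groups, empty epochs) return missing or maximal-p results
rather than errors wherever the quantity is well-defined as a limit.

## Known limitations

* The KS p-value is an asymptotic bound; at very small cell counts it is
  conservative relative to the exact tail.
* Bout censoring at epoch boundaries is not modeled; for epochs of hours and
  bouts of seconds the effect is negligible.
* `simulate_plate` restarts the bout process at epoch boundaries rather than
  carrying a bout across the light transition.
* The clustergram assumes a complete pairwise-valid dissimilarity; it
  refuses (rather than imputes) under-supported pairs.
* No dose–response structure in libraries, no multivariate tests on
  fingerprints, no count-model fitting for bulk regions (their output table
  is consumed, not produced).
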