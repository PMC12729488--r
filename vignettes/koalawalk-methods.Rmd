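---
title: "Methods: from collar signal to ground-visit statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from collar signal to ground-visit statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`koalawalk` re-implements, end to end, an accelerometry-to-behaviour
analysis for a collared arboreal mammal: a tri-axial collar samples
acceleration at 50 Hz, a supervised classifier turns windowed signal
features into per-second behaviour labels, and a rule-based post-processing
chain turns those labels into behavioural budgets, ground-visit statistics
and diel activity curves. This vignette records the model assumptions, the
parameters that matter, and the design decisions taken where the procedure
was genuinely open.

## The signal model and its assumptions

Acceleration at the collar is treated as static (gravity) plus dynamic
(movement). The static component per axis is a centred 2 s rolling mean
(shrunken at the edges); the dynamic residual defines

* VeDBA, the Euclidean norm of the dynamic 3-vector, and
* ODBA, its 1-norm analogue,

so ODBA ≥ VeDBA ≥ 0 at every sample and VeDBA is invariant to a static
re-orientation of the collar. The 2 s smoothing window is the convention of
the dynamic-body-acceleration literature; it is exposed as `smooth_s` and
passes a 2 Hz gait oscillation essentially unattenuated (a boxcar over an
integer number of cycles averages to zero). Whether the original analysis
derived VeDBA from a smoothing decomposition or a band-pass filter is not
stated anywhere we could rely on; the decomposition was chosen because it
is exact (static + dynamic = raw) and assumption-light.

## The synthetic deployment

No field data are distributable, so the package's first-class citizen is a
generator that emulates the study conditions: nine collared animals, eight
days each, 50 Hz, with the behaviour repertoire used for classification
(Still, In-tree Movement, Climbing, Feeding, Grooming, Bellowing, Walking).

**Bout structure.** Behaviour sequences are semi-Markov: each bout draws an
explicit gamma dwell time (e.g. mean 20 min for Still, 45 s for Climbing),
and the probability of *entering* a behaviour is modulated over the 24 h
cycle by a cosine bump centred on that behaviour's peak hour
(motionlessness in the morning, in-tree movement early afternoon,
feeding/grooming early evening). Entry weights are calibrated by a
fixed-point iteration so that the long-run time share of each behaviour
matches its configured budget despite the diel modulation; the law of
large numbers check at 100 simulated days holds within 5 % relative error
for all non-trace behaviours. Explicit dwell distributions (rather than
per-second transitions) are what make the sub-3 s blip-collapse rule
testable: bout lengths, not just time shares, are controlled.

**Ground visits.** Walking is overlaid as a time-inhomogeneous visit
process: daily visit counts are Poisson at the individual's rate, start
hours follow a 24-vector of weights concentrated in the 02:00–05:00 window
(with the strongest weight in its first hour), and per-visit walking
duration is 20 s plus a lognormal excess. Two calibration decisions matter
here:

1. *Individual movement strategies.* The published population means —
   2.95 visits/day, 1.59 min walking per visit, and 3.0 min walking per
   day — are mutually inconsistent for identical animals
   (2.95 × 1.59 ≈ 4.7 ≠ 3.0). Because the original summaries average
   within individuals before averaging across them, all three numbers can
   hold simultaneously only if visit rate and mean visit duration are
   negatively related across animals (frequent-short versus rare-long
   movers). `individual_profile()` therefore assigns each animal a fixed
   rate from a lognormal-quantile ladder and the duration `3.0 / rate`, so
   the population means reproduce all three published values exactly. The
   profile is deterministic given the configuration — heterogeneity is a
   trait, not a random draw — which keeps the nine-animal mean stable
   enough to be a useful recovery target.
2. *The 20 s observational floor.* Published per-visit durations are
   20 s-bin quantities: no visit shorter than a bin's majority (~10 s of
   walking) is observable by any binning pipeline, and the shortest
   reportable visit is one 20 s bin. Simulating lognormal mass below that
   floor would make the configured rate unrecoverable by construction, so
   the generator models visit duration as `visit_min_s` (default 20 s)
   plus a lognormal excess with the configured mean preserved.

**Signal signatures.** Each behaviour has a static orientation (unit
gravity vector), a dynamic amplitude, a dominant frequency and a
burstiness (fraction of the bout occupied by one-second movement bursts).
Walking is a near-continuous 2 Hz oscillation at 3 m·s⁻²; Still is
near-zero noise; feeding and grooming are intermittent bursts; climbing is
large, slow excursions. Per-bout jitter (±10 % tempo, lognormal vigour,
~5° posture wobble) keeps windows from being carbon copies. The in-tree
behaviours deliberately share near-identical postures and overlapping
amplitudes (Feeding 0.8 vs In-tree Movement 0.7 m·s⁻²), so the classifier
must work from dynamics and the feeding-versus-movement confusion of real
deployments is reproduced rather than abstracted away. Canopy sway is an
additive 0.2 Hz sinusoid (default 0.05 m·s⁻², configurable) applied only
to in-tree samples — the mechanism by which wind makes resting animals
look active. No quantitative per-behaviour amplitudes were available to
copy; the defaults were fixed once so that the mean-VeDBA ordering
Walking > Feeding > Still holds, and are otherwise placeholders.

**What the generator does not emulate:** biomechanically realistic gait,
GPS movement, temperature effects, collar slippage, or long recording
gaps. Passing tests on synthetic data therefore demonstrates that the
*pipeline* is correct and recoverable under the stated statistical
structure, not that the classifier would reach the same accuracy on field
data.

## Classification

Windows are 1 s with 50 % overlap — overlap acts as oversampling and
keeps transitions visible. A window inherits the majority per-sample label
if that label covers at least 70 % of the window (the original procedure
does not say how mixed windows were labelled; 70 % is this package's
threshold, exposed as `purity`); windows below the threshold train
nothing. The split is chronological per (behaviour, individual): first
60 % training, middle 20 % validation, last 20 % test, so no behavioural
sequence spans two sets; strata under five windows go wholly to training.

The forest's three hyperparameters (number of trees, mtry, max depth) are
searched over trees ∈ [100, 1000], mtry ∈ [⌈√p⌉/2, p/2], depth ∈ [4, 32],
maximising validation macro-F1. The search is pluggable and
seed-deterministic; this build ships uniform random search and a grid
fallback (the original used Bayesian optimisation, for which no
implementation is available here — with three integer-ish dimensions and
typical budgets the difference is marginal). Per-second prediction uses
the window starting at each clock second; off-grid windows serve training
only.

Evaluation reports per-class precision, recall, F1 (harmonic mean, 0 when
degenerate) and *balanced* accuracy ((recall + specificity)/2): the
published per-class "accuracy" for the rarest class is consistent with
balanced accuracy and not with raw accuracy, so that interpretation is
adopted and documented. Macro rows are unweighted class means — the
convention that exactly reproduces the published macro values from the
per-class rows.

## Post-processing chain

Per-second labels pass through, in order: a centred 5 s modal filter (ties
retain the original centre label; edges use shrunken windows); collapse of
runs shorter than 3 s into the surrounding state — agreeing flanks take
that state, disagreeing flanks take the longer flank with ties to the
preceding state, interior runs first and edge runs (which have a single
neighbour) last; LOCF/NOCB fill for missing seconds; regrouping to
General Movement in Tree, Motionless in Tree, Feeding & Grooming in Tree,
Walking, and Other (excluded from all downstream summaries, with its share
reported and a warning above 5 %); and non-overlapping 20 s majority bins
(ties to the bin's central second, consistent with the modal filter's
centre convention) carrying the means of within-second VeDBA maxima and
minima. Raw VeDBA seconds are retained under relabelled bins. After the
collapse step every surviving run is at least 3 s, which makes the modal
filter the identity on its output — the chain is exactly idempotent from
the second application onward, and the test suite checks this against
brute-force reference implementations on randomized sequences. The bin
grid is anchored at local midnight (UTC+10, no DST), so hour-of-day
aggregation is exact.

## Ground visits, budgets, diel models

A Ground Visit is a maximal cluster of Walking bins with inter-bin gaps
≤ 60 s; visit duration resolution is one bin (20 s). Days are
local-midnight aligned; a visit belongs to the day containing its start;
visit rates divide by recorded days only. Daily budgets rescale recorded
time to 1440 min before computing percentages (gaps are rescaled over,
not imputed), exclude days under one recorded hour, and summarise by
averaging within individuals across days before averaging across animals.

Diel curves are GAMMs fitted by REML in `mgcv`: a cyclic cubic spline over
hour-of-day (knots at 0 and 24, so predictions at 0 h and 24 h coincide by
construction) plus a random intercept per individual, dropped with a flag
when only one animal is present. The VeDBA curve is Gaussian with a ±1
residual-SD ribbon; the Walking curve models per (individual, day, hour)
bin counts as binomial on the logit scale with 95 % CI ribbons — the
original does not state its response family for proportions, and binomial
counts use the available information without an ad-hoc empirical-logit
transform. A constant response has no REML solution and is returned as an
explicitly flat curve. VeDBA comparisons across categories use
Kruskal–Wallis followed by all pairwise two-sided Wilcoxon tests with
Benjamini–Hochberg correction on log-transformed values (the rank tests
are invariant to the log, which is kept for fidelity and for the reported
medians); ties use mid-ranks with the normal approximation. Sex and
habitat effects on daily Walking minutes use a linear mixed model with an
individual random intercept and Satterthwaite F tests.

Published effective-degrees-of-freedom, F and R² values of the field fits
are *not* targets: they depend on unavailable field data. The package
reproduces the modelling procedure and its qualitative outputs (peak
positions, orderings, significance patterns) on synthetic data.

## Problem sizes and numerical choices

The test suite exercises the full stack at sizes chosen to be informative
per CPU-minute: the classifier fixture trains on two simulated captive
animals × 2 h (≈ 29 000 labelled windows) and scores two wild animals ×
1 day at 50 Hz; the parameter-recovery fixture runs the ground-truth label
path for the full 9 × 8-day deployment (6.2 M labelled seconds); oracle
checks use 1000 randomized label sequences and 1000-bin visit fixtures.
Recovery outcomes at these sizes: test-set macro-F1 ≈ 0.92 with the
feeding/movement confusion concentrated exactly where intended; recovered
visits/day 2.5–3.0 against the configured 2.95; recovered daily walking
within ±0.3 min of the configured 3.0; fitted walking peak inside
02:00–05:00. Degenerate inputs are mapped to defined sentinels (zero
variance → correlation/skewness/kurtosis/entropy 0), seeds derive
per-individual child seeds below 2³¹, and acceleration is clipped at ±4 g
to mimic the logger range.

## Known limitations

* Classifier accuracy on synthetic signatures is optimistic relative to
  field deployments; the captive→wild domain shift is emulated only
  through canopy sway and signature overlap.
* Ground visits count only detected Walking; non-walking ground behaviour
  is invisible, so visit durations are conservative.
* Sub-bin (< ~10 s walking) ground visits are unobservable at 20 s
  resolution — an instrument property the generator mirrors by
  construction rather than a correctable bias.
* The tap detector assumes taps dominate the dynamic norm (≥ 3 g); softer
  calibration gestures would need a lower threshold and stricter grouping.
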