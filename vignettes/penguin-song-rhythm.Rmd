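---
title: "Quantifying accelerando and crescendo in penguin display songs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying accelerando and crescendo in penguin display songs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Male African penguins advertise with multisyllabic *ecstatic display
songs*: a run of short egressive A syllables culminating in one long, loud
B syllable, sometimes with ingressive C syllables (audible breaths)
interspersed. Listeners report that these songs speed up and get louder as
they progress. This package turns those impressions into testable
quantities: inter-onset-interval (IOI) statistics, acceleration ratios,
binned timing-precision measures, and a suite of nested mixed-effects
models, together with a principled procedure for deciding whether breaths
belong to the song's temporal stream.

The unit of analysis is the song **up to and including its first B
syllable**. Truncation happens once, at read time, and everything
downstream assumes it; songs without a B syllable are rejected (or skipped
in batch mode) because the display's terminus anchors both the rhythm and
the intensity reference.

# Rhythm primitives

For n retained syllables there are n−1 onset-to-onset IOIs. Each IOI
decomposes as `ioi = syllable_duration + silence`, where the syllable is
the interval-opening one; the B syllable contributes only its onset.
Acceleration ratios `a_i = IOI_i / (IOI_i + IOI_{i+1})` compare
neighbouring intervals: 0.5 is isochrony, above 0.5 acceleration. For
geometric IOI decay with per-step factor r every ratio equals `1/(1+r)`,
which is the closed form the tests lean on. The song-level acceleration
summary averages `a_2 … a_{n-2}`, excluding the single ratio that involves
the first IOI so that it can later be regressed on the first IOI without
circularity; it therefore needs n ≥ 5, and 4-syllable songs contribute
ratios but no song-level average.

Relative positions scale any ordered sequence to [0, 1] as
`(i−1)/(count−1)`; for one song the syllable, IOI and ratio sequences use
denominators n−1, n−2 and n−3. Binned variability pools each penguin's
IOIs across songs into five bins `[0,0.2) … [0.8,1]` (final bin closed so
the last IOI is always counted) and reports the coefficient of variation
with the standard small-sample correction `(1 + 1/(4n))·SD/mean`. The
correction factor is the usual first-order unbiasing term; bins with fewer
than two IOIs are flagged undefined rather than extrapolated. Pooling IOIs
across a penguin's songs (rather than averaging per-song CVs) is the
implemented convention: it measures the repeatability of the penguin's
timing program at each song position.

# The C-syllable decision

Breaths could either sit inside silent gaps without disturbing the
egressive beat, or occupy genuine beat slots. The package decides
empirically. Ratios computed on the egressive stream are *baseline* when
no C onset falls strictly inside either of their two constituent IOIs
(half-open `[start, end)` spans); otherwise the region is C-affected and
contributes its egressive ratio to the *C-omitted* set, while every ratio
of the all-syllable stream whose onset triple contains a C goes to the
*C-included* set (one C adds one onset, hence one extra IOI and up to
three affected ratios — all are kept).

A Gaussian KDE is fitted to the pooled baseline ratios (equal-weight
normal mixture, Silverman bandwidth by default, so the density is exact
and evaluable anywhere). Pooling across penguins follows from treating the
baseline as one population-level reference distribution; a per-penguin
variant would need far more C-free material per bird than six songs
guarantee. For each penguin with at least three C syllables, the medians
of the baseline density at its C-omitted and C-included ratios are
compared by a paired two-sided Wilcoxon signed-rank test (exact null for
n ≤ 25, zero differences dropped; the reported T is the smaller rank sum).
The verdict — omit or include C onsets downstream — follows the sign of
the median difference when the test rejects, and defaults to omission
otherwise. Both directions are exercised in tests: the generator's breath
mode must yield "omit", its rhythmic mode "include".

# The inference suite

All mixed models are fitted with `lme4` by **maximum likelihood** (not
REML), because the likelihood-ratio comparison removes a fixed effect and
REML likelihoods are not comparable across fixed-effect structures. Each
test refits the null with the identical random structure and reports
`chi2 = 2·(ll_full − ll_null)` on 1 df, clamped at zero against numerical
noise. "Song in penguin in colony" is implemented as random intercepts at
colony, penguin-within-colony and song-within-penguin; grouping factors
with fewer than two observed levels are dropped with a message so the same
code runs on single-colony subsets.

* **Accelerando**: `ln(IOI) ~ relative position`. A linear slope β in log
  space is an exponential tempo curve; `100·(e^β − 1)` is the percent IOI
  change over the whole song, and `exp(β)` is exactly the model-predicted
  IOI at position 1 over position 0.
* **Constancy**: `ratio ~ relative position` asks whether the acceleration
  itself drifts along the song.
* **Components**: `ln(syllable)` and `ln(silence)` against the IOI's
  position decompose the accelerando. Zero-length silences (abutting
  annotations) cannot enter a log model and are excluded with a logged
  count rather than offset-shifted — pseudocounts would manufacture a
  floor effect.
* **Precision**: `binned CV ~ bin position`, random intercepts penguin in
  colony (bins are already per-penguin summaries, so no song level).
* **Plasticity**: `average acceleration ~ first IOI`, penguin in colony;
  with penguin identity absorbed by the random intercepts the fixed effect
  is within-penguin tempo compensation.
* **Crescendo**: `intensity relative to the first B ~ syllable position`,
  with correlated random intercept+slope terms at the penguin and song
  levels (slope-only variation at colony level is rarely identifiable with
  three colonies and is not attempted). The B syllable itself sits at
  position 1 with normalized intensity 0 and is included by default
  (`include_b = FALSE` drops it). With only three colonies the colony
  variance is frequently estimated at zero, so plain singularity is
  reported but tolerated; the model downgrades to nested random intercepts
  only when the slope fit fails outright or both slope variances collapse,
  otherwise the random-slope specification would be dead code.

Per-penguin ordinary least-squares regressions (same response/predictor
definitions, random effects dropped) accompany the accelerando, plasticity
and crescendo models, with a count of significant slopes in the expected
direction at two-sided α = 0.05.

## CV equality

First-versus-last IOI variability per penguin is tested with a modified
signed-likelihood ratio test for CV equality of two normal samples. Under
the null of a common CV τ, the per-group mean solves
`n·τ²·μ² + S₁·μ − S₂ = 0` in closed form, leaving a one-dimensional
profile maximization over τ. The signed root `R = sign(cv₁−cv₂)·√LR` is
only asymptotically standard normal; the implementation standardizes it by
its null mean and SD estimated from parametric Monte-Carlo replicates at
the fitted null (200 by default). Centering alone proved insufficient in
simulation — for balanced two-sample designs the root is nearly unbiased
but over-dispersed (null SD ≈ 1.04 at n = 20) — so the correction uses
both moments. A label-permutation test on mean-scaled samples serves as
the independent oracle in the test suite. Degenerate inputs (both samples
constant) return p = 1 with a flag instead of failing.

# The synthetic generator

The generator exists to make every stage testable, so its core principle
is that **the generating model is exactly the model being fitted**. Log
IOIs are linear in relative position with multiplicative lognormal jitter,
so the accelerando LMEM is correctly specified; random intercepts
(lognormal, 0.05 log units by default at colony, penguin and song levels)
act on the first-IOI level, matching the fitted nested-intercept
structure. Parameter defaults are the study conditions: 3 colonies, 26
penguins, 6–20 A syllables per song, median first IOI 0.5 s, total IOI
decay `ln 0.75` (−25%), syllable growth `ln 1.2` (+20%) from an initial
syllable fraction 0.3 of the first IOI — which forces the end-of-song
silence to `(0.75 − 0.3·1.2)/0.7` of its start, a 44–45% decrease — jitter
SD falling 0.08 → 0.03 along the song, a 12 dB crescendo peaking at the B
syllable, and songs-per-penguin 20 (the corpus the study scale implies is
roughly 500–550 songs from 26 males).

Two modelling choices deserve justification. First, the coupling between
the first IOI and the song's acceleration acts on the *within-penguin*
deviation of the first IOI from the penguin's habitual tempo
(`β_song = β + k·(IOI₁ − E[IOI₁ | penguin])`, default k = −0.6 log-slope
units per second). Coupling to the population expectation instead would
let the realized colony/penguin intercepts shift the population mean
slope, confounding the accelerando recovery; the within-penguin form
matches what the plasticity model isolates. Second, syllable durations
carry their own small lognormal jitter (0.05): perfectly deterministic
durations would give the syllable-duration model a zero residual variance
and a degenerate likelihood.

C syllables are added from a separate random substream per song, so a
breath-mode dataset has byte-identical egressive onsets to its same-seed
C-free twin — the exact property the C-analysis must detect. Breath mode
places a C in the middle 40% of a silent gap; rhythmic mode relabels an
interior beat slot as ingressive. Songs whose jittered draws would produce
a non-positive silence are redrawn (cap 100, then a configuration error);
configurations whose deterministic part cannot keep silences positive are
rejected up front.

Because the implied log-silence trajectory
`log(e^{βp} − f·e^{γp})` is smooth but not exactly linear,
`implied_slopes()` computes the silence "truth" as the least-squares
projection of that curve onto position (and the plasticity truth by
numerically differentiating the noise-free average acceleration at the
expected first IOI, at the median song length). Parameter-recovery tests
compare fitted estimates to these implied values within 3 SE at the
26 × 20 scale.

What the generator does *not* emulate: spectrally realistic penguin voices
(the audio renderer produces harmonic bursts sufficient for testing the
intensity extractor, nothing more), non-stationary season or arousal
effects, unbalanced song counts, annotation error, or overlapping singers.
Passing tests therefore show that the pipeline recovers the structure it
assumes when that structure is present — not that real songs obey the
model; on real data the mixed models remain interpretable as linear
approximations.

# Numerical conventions and limitations

* Time is seconds, intensity dB throughout; natural logarithms everywhere;
  percent changes are `100·(e^β − 1)` across the full song.
* Intensity is Praat-style: a Hann band-stop removes energy below 100 Hz
  (10 Hz transition, applied as a spectral mask), then Hann-windowed frame
  powers (32 ms window, 8 ms step — typical contour defaults, exposed as
  arguments since the method does not fix them) are averaged on the energy
  scale, `10·log10(mean power)` against the 4e-10 reference. Silent
  segments return a flagged `NA`, never −∞.
* The TextGrid reader parses both long and short `ooTextFile` forms,
  interval tiers only; labels other than A/B/C are validation errors with
  the offending time. CSV round trips preserve times to better than 1 ns.
* Exact bin edges: a relative position equal to an edge falls in the upper
  bin; position 1.0 falls in bin 5.
* The Wilcoxon comparison is exact for n ≤ 25 eligible penguins and
  normal-approximate beyond; KDE bandwidth and kernel are configurable and
  logged in the fitted object.
* Simulation scales in the test suite (e.g. 200 null datasets of 8
  penguins × 6 songs for size calibration; 100 seeds per C-mode for the
  discrimination check; 1000 replicates for CV-test calibration) were
  chosen as the smallest designs whose Monte-Carlo error is well inside
  the tolerances being asserted.
* Known limitations: the CV-equality test assumes normal samples (IOIs are
  mildly lognormal; the permutation oracle guards the conclusions); the
  crescendo model assumes the B syllable is a stable per-song reference;
  and with three colonies the colony-level variance is rarely
  identifiable, which is reported but intentionally not "fixed".
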