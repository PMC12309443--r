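# penguinsong

Quantitative rhythm and intensity analysis of African penguin
(*Spheniscus demersus*) ecstatic display songs, for bioacousticians who
have syllable-level annotations (Praat TextGrids or CSV tables) and want
to test whether songs speed up (*accelerando*), get louder (*crescendo*),
and become more precisely timed as they progress — and whether audible
breaths take part in the song's temporal structure.

## What it computes

A song is the run of short egressive **A** syllables up to and including
the first long **B** syllable, possibly with ingressive **C** syllables
(audible breaths) interspersed. From the n retained syllable onsets the
package computes the n−1 inter-onset intervals (IOIs), their silent and
syllable components, and the n−2 acceleration ratios

&nbsp;&nbsp;&nbsp;&nbsp;a&#8342; = IOI&#8342; / (IOI&#8342; + IOI&#8342;&#8330;&#8321;),

where a = 0.5 is isochrony, a > 0.5 acceleration, a < 0.5 deceleration.
A song-level acceleration summary averages a&#8322;…a&#8345;&#8331;&#8322;
(excluding the only ratio that uses the first IOI). Timing precision is
summarized by the small-sample-corrected coefficient of variation
(1 + 1/(4n))·SD/mean of IOI durations in five relative-position bins.

On top of these primitives the package provides:

* **C-syllable stream membership** — acceleration-ratio distributions are
  built three ways (baseline regions without Cs; C-affected regions with C
  onsets omitted; the same regions with C onsets included), the two
  alternatives are scored under a Gaussian KDE of the baseline, and a
  paired per-penguin Wilcoxon signed-rank test decides whether C onsets
  should enter the IOI arithmetic.
* **The mixed-model inference suite** — six `lme4` models fitted by ML
  with chi-square likelihood-ratio tests on the single fixed effect:
  log IOI, acceleration ratio, log syllable duration and log silence
  against relative position (random intercepts for song in penguin in
  colony); binned CV against bin position (penguin in colony); average
  acceleration against the first IOI (penguin in colony); and normalized
  intensity against syllable position with random position slopes.
  Per-penguin OLS regressions mirror each headline model.
* **CV equality** — a modified signed-likelihood ratio test for equality
  of two coefficients of variation (profile likelihood, Monte-Carlo
  small-sample standardization), applied per penguin to first-versus-last
  IOIs, with a permutation oracle for validation.
* **A synthetic song generator** — exponential IOI decay with shrinking
  lognormal jitter, growing syllable durations, a linear-in-position
  crescendo, first-IOI/acceleration coupling, nested random intercepts,
  and breath-mode or beat-mode C syllables, so the entire pipeline is
  testable without field recordings. `synthesize_song_audio()` renders
  songs to audio for testing the Praat-style intensity extractor
  (sub-100 Hz band-stop, Hann-windowed energy mean).

## Worked example

```r
library(penguinsong)

dataset <- generate_dataset(synthetic_song_config(seed = 20260923L,
                                                  c_mode = "breath"))
report <- run_pipeline(dataset, include_c = "auto")
print(report)
```

Output from this exact run:

```
Song dataset: 3 colonies, 26 penguins, 520 songs
  syllables: A=6810 B=520 C=655
C-syllable analysis: verdict 'omit' (Wilcoxon T = 0.0, p = 0.00024, n = 13 penguins)
Mixed-model suite:
  accelerando: log IOI ~ relative position                est  -0.2911  chi2(1)  7902.552  p <2e-16  n 6810
  acceleration constancy: ratio ~ relative position       est  -0.0001  chi2(1)     0.010  p 0.919  n 6290
  syllable duration: log duration ~ relative position     est   0.1824  chi2(1)  5546.451  p <2e-16  n 6810
  silence duration: log silence ~ relative position       est  -0.5900  chi2(1)  9516.694  p <2e-16  n 6810
  IOI variability: binned CV ~ bin position               est  -0.0711  chi2(1)   212.161  p <2e-16  n 130
  tempo plasticity: average acceleration ~ IOI1           est   0.0138  chi2(1)    47.406  p 5.77e-12  n 520
  crescendo: normalized intensity ~ syllable position     est  11.9768  chi2(1)   198.842  p <2e-16  n 7330
Per-penguin accelerando: 26/26 penguins with significant negative slope
CV equality (first vs last IOI): 12/26 penguins with significant decrease
```

Reading it: the Wilcoxon T = 0 means every eligible penguin's C-omitted
ratios match the baseline better than its C-included ratios, so breaths
are dropped from the IOI arithmetic. The accelerando slope −0.2911 in log
space means IOIs shrink by 100·(e^−0.2911 − 1) ≈ −25% over a song; the
component models attribute that to silences (−44.6%) rather than
syllables (+20.0%); the falling binned CV means timing gets more precise;
the positive plasticity slope means slow-starting songs accelerate
harder; and the crescendo slope is ~12 dB per unit song position.

To run the same analysis on real annotations, point
`read_csv_table()` at a syllable table (columns `colony_id, penguin_id,
song_id, label, onset_s, offset_s[, intensity_db]`) or build a dataset
from TextGrids with `read_textgrid()` + `as_song_dataset()`.

The numbered drivers in `analysis/` run the same workflow as a script
sequence (`01_simulate.R`, `02_c_syllable_analysis.R`,
`03_rhythm_models.R`), writing their tables under `results/`.

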