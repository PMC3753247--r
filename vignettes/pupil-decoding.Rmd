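---
title: "Decoding concealed choices from pupil dilation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding concealed choices from pupil dilation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilrps)
```

## The problem

When a person covertly commits to a decision, their pupil transiently
dilates. In a rock-paper-scissors setting where the three words are read
aloud at 4-s intervals and the opponent silently selects one as it is
spoken, the *time of maximum pupil dilation* becomes a physiological marker
of the concealed choice: the global diameter maximum tends to fall shortly
after the selected word. This package simulates that entire experimental
situation — opponent pupil traces, the peak-timing decoder, players who
exploit (or ignore) the decoded signal, and the statistics used to judge
performance against the 1/3 chance level.

Everything here operates on synthetic traces: the generator is the study's
data source, and its defaults define the study conditions.

## The trace model

A game's trace is sampled at 120 Hz for 14 s (word onsets at 1, 5, 9 s —
the 4-s spacing of the spoken words, plus a ~4-s response window after the
last word) and is built additively:

* a constant baseline diameter (default 3.87 mm);
* one *decision-locked transient* at the selected word's onset: a
  gamma-shaped impulse response `(t/tp)^s exp(s(1 - t/tp))`, normalised to
  peak 1 at `tp`, with peak latency `tp = 1.5` s and shape `s = 6` (fast
  rise, slower decay, essentially returned to baseline before the next
  word). The observed dilation curve constrains only "a peak shortly after
  the selected word", so the latency is a modelling judgement; the gamma
  family is the standard parametric form for pupillary impulse responses;
* optional *distractor transients* at each non-selected onset (inclusion
  probability 0.7), representing dilation attributable to hearing and
  evaluating a word that was not chosen — plus any motor/arousal components
  that the single-kernel model does not separate;
* additive white measurement noise (SD 0.05 mm).

Per-game transient amplitudes are drawn as truncated normals: the selected
transient as N(3.2, 1.3) mm and distractors as N(2.5, 1.2) mm. Samples are
floored at 0.5 mm (with a warning) because a physical pupil diameter cannot
approach zero; under the defaults the floor is never reached.

### Calibration

The amplitude, baseline and noise defaults were chosen once so that a
75-game set reproduces the target trace statistics: grand-mean diameter
4.6 mm, mean within-game (max − min) range 3.8 mm, SD of ranges across
games 1.0 mm. Over 12 calibration seeds the defaults give 4.60 / 3.87 /
1.05 mm. The overlap between selected and distractor amplitude
distributions puts the *natural* probability that the global maximum
follows the selected word at ≈ 0.58, conveniently close to the 60%
marker validity that the generated sets enforce exactly.

```{r calibration}
fixture <- reference_fixture()
summarize_traces(fixture)
validity(fixture)
```

### Exact validity control

Marker validity — the fraction of games whose global maximum falls in the
selected interval — is enforced exactly, not in expectation: each game is
assigned a target flag (valid/invalid) and its trace is regenerated until
the decoder agrees with the flag (rejection sampling, capped at 1000
attempts per game; the cap only triggers if a configuration makes the
requested validity unreachable, e.g. demanding invalid games from a
noise-free single-kernel setup). This is simpler and more exact than
analytically tuning amplitudes, at the cost of slightly distorting the
amplitude distribution conditional on validity — immaterial here, because
every downstream quantity conditions on the decoded/selected agreement
itself.

The packaged `reference_fixture()` is a deterministic 75-game set generated
from a fixed internal seed: 28/25/22 selections of intervals 1/2/3, exactly
45 valid games split (16, 15, 14) across intervals. Only "at least 10 valid
per interval" is structurally required (so the 100%-validity selection can
succeed); the specific split is arbitrary. With 45 of 75 valid, the marker
validity is exactly 60%.

## The decoder

`decode_games()` takes the global maximum of the diameter inside the
analysis window and attributes it to the latest word onset at or before the
peak. Window and tie policy:

* the window starts at the first onset — a peak before any word cannot
  "follow" a word — and runs to the trace end, with half-open interval
  attribution `[onset_i, onset_{i+1})`, the last interval extending to the
  trace end;
* ties at the maximum break to the earliest sample, making the decode fully
  deterministic;
* no smoothing is applied by default (`smooth_width_s` exposes an optional
  moving average). Whether the peak should be found on raw, smoothed or
  z-scored data is underdetermined; since the argmax is invariant under
  positive affine transforms, per-opponent z-normalisation
  (`znormalize()`) provably cannot change the decode — a property the test
  suite checks — so only smoothing is a real analysis choice, and it is off.

## Players and strategies

Players are modelled by a single *follow probability*: with probability `f`
they play the counter-move of the decoded choice, otherwise they choose
uniformly. Following wins exactly when the decode is correct (a wrong
decode means the true choice draws with or beats the player's counter), so
the expected win rate has the closed form `f·v + (1 − f)/3` for marker
validity `v` — the oracle used to verify the Monte-Carlo simulations.

Condition defaults in `run_condition()` / `replicate_study()`:

| condition | games | follow probability |
|---|---|---|
| `naive_eye` | all 75 | 0 (group performance indistinguishable from chance) |
| `informed_eye` | all 75 | 1 (upper bound; real groups sat below the 60% ceiling, so `follow_prob` is exposed as a knob) |
| `reconstructed_pupil` | all 75 | 1 (computationally identical to informed-eye; the pupil-only stimulus difference is perceptual) |
| `no_video` | all 75 | 0 |
| `naive_100pct` | 30-game 100%-valid subset × 4 blocks | block ramp 0, 1/3, 2/3, 1 |

The block ramp is a *descriptive* stand-in for within-session learning, not
a mechanistic learning model; idiosyncratic naive heuristics reported in
debriefings (constriction-following, blink cues) are not modelled. The
100%-validity subset takes, per interval, the first 10 decoder-valid games
in chronological order (ascending `game_id`, the only chronology synthetic
data has), then repeats them in 4 independently shuffled blocks.

## Statistics

* **Individual tests**: exact one-sided binomial upper tail
  `P(K ≥ k | n, 1/3)` (one-sided because learning can only improve
  performance), evaluated through the regularized incomplete beta function
  and verified in the tests against brute-force summation to 1e-12 relative
  error. With 10 players per condition, significance is declared below the
  Bonferroni-corrected 0.05/10 = 0.005.
* **Learning curves**: after every game the cumulative win count over all
  preceding games is tested; `significance_boundary()` gives the per-n
  minimal significant win count (the "5% line" over a cumulative-wins
  plot), brute-force-verified for n ≤ 200.
* **Group tests**: two-sided t-tests of win fractions against chance
  (33%); the unpaired form uses pooled-variance Student's t (the
  conventional default for this design; Welch available via
  `var_equal = FALSE`). Zero-variance inputs arise in deterministic
  simulations and are reported as `p = 1` when the means agree with the
  null and `p = 0` with a warning when they do not (the t statistic being
  undefined either way).

```{r stats}
binomial_tail(75, 37)[, c("n", "k", "p_value", "significant")]
```

## What the simulations do and do not show

The generator reproduces the *statistical envelope* of real opponent
traces: sampling rate, grand mean, within-game range, the decision-locked
peak, and an exactly controlled marker validity. It does not emulate
blinks or segmentation artifacts (off by default; the pupil-only stimulus
condition shows the diameter signal alone suffices), luminance or
accommodation responses, inter-opponent baseline differences, or human
sequential-choice biases (game order is randomised per session, making
history uninformative by design). Draw/loss splits are not modelled targets
— only win counts are reproduced. Passing tests therefore validate the
decoding-and-statistics pipeline and the closed-form performance model,
not any claim about new empirical pupil data.

Group t-statistics from the original study depend on unpublished per-player
win counts and cannot be recomputed here; the group-level machinery is
exercised on simulated players instead.

## Problem sizes and numerical choices

The shipped analyses use the study's own sizes: 75-game sets, 10 players
per condition, 30-game × 4-block sessions, 10,000-game chance controls, and
1,000 null sessions for the type-I calibration check. Stochastic
assertions use 3–4 standard-error tolerances with fixed seeds. All
generation is reproducible bit-for-bit from an integer seed; trace CSVs are
written at full double precision so a round-trip through
`write_game_set()` / `read_game_set()` cannot move the decode argmax.
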