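---
title: "Measuring and comparing the prosody of filled pauses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing the prosody of filled pauses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hesitone)
```

## The analysis in one paragraph

Filled pauses ("äh"/"ähm", English "uh"/"uhm") are usually produced with a
flat intonation contour. `hesitone` quantifies how far a corpus of dyadic
conversation departs from that convention and whether two groups of speakers
differ in doing so. From time-aligned annotations (Praat TextGrids) and F0
tracks (Praat PitchTiers) it builds a token table, measures each token's
pitch movement as a semitone difference between two near-edge points,
classifies the movement as rise, level or fall, summarises speakers and
dyads (rate per minute, uh-vs-uhm choice, duration-based role proportions,
Shannon entropy of contour use), and estimates group contrasts with
Bayesian count, proportion and scalar models that report a posterior mean
difference, its 95% credible interval and P(δ > 0).

## The measurement model

**Semitone scale.** Pitch differences are computed in semitones,
`12 * log2(f2 / f1)`, which makes them independent of a speaker's register:
the same melodic movement gives the same value at 120 Hz and at 220 Hz.
Absolute values use a 1 Hz reference; the reference cancels in differences
but keeps single points reportable.

**Near-edge points and the fallback rule.** A token's movement is the ST
difference between the points at 10% and 90% of its duration — inside the
edges, because microprosody and glottalization corrupt F0 at syllable
boundaries. When F0 is undefined at a nominal point (unvoiced or non-modal
stretches), that point moves inward in steps of 10% of token duration, to at
most 40% at the start and 70% at the end. The two edges move
*independently*, and each only while undefined: a dropout at the start must
not discard a perfectly good 90% point, and mixed windows such as 20–90% or
10–80% are exactly what this produces. A token is excluded — with the reason
recorded — when either edge exhausts its grid, since a difference needs both
points. Exclusions are never silent; the pipeline report itemises them.

**Interpolation.** PitchTier samples are interpolated linearly, but only
within a voiced run: two samples further apart than `max_gap` (default
0.02 s, i.e. two standard 0.01 s pitch frames) are treated as separated by a
genuine unvoiced region, and queries inside that gap, before the first or
after the last sample are undefined rather than extrapolated. An optional
3-point running-median smoother (`smooth = TRUE`) is available as a fully
automated, transparent alternative to hand-corrected contours; it is off by
default so that what is measured is always what was in the file. Likewise
optional (`flag_implausible = TRUE`) is a plausibility screen that flags
movements exceeding 12 ST within less than 100 ms — physiologically
implausible for a filled pause — replacing a manual verification pass with a
reproducible rule.

**Classification.** A movement within ±1 ST counts as level; only values
strictly exceeding the band are rises (positive) or falls (negative). The
boundary is therefore classified level by construction, and the threshold is
a parameter (`threshold_st`) so its influence can be examined; shrinking it
can only shrink the level share.

**Diversity.** Per speaker, the three category proportions are summarised
by Shannon entropy in bits, `H = -sum(p * log2(p))` with `0 log 0 = 0`. Base
2 fixes the ceiling for three categories at `log2(3) ≈ 1.585`: 0 means one
contour used throughout, the maximum means all three used equally. Note that
a speaker who consistently *falls* instead of staying level also gets a low
H — entropy measures diversity, not conformity to the level convention,
which is why the pipeline reports both the level proportions and H.
Speakers without a single analyzable token are dropped from proportion and
entropy analyses rather than zero-filled.

## The comparison models

Three model structures cover every contrast:

* **Rates** — dyad token counts with a negative-binomial likelihood, log
  link and log-exposure offset. Exposure is in *speaker-minutes* (twice the
  dialogue duration, both partners contributing), so the group coefficient
  is a log rate ratio per speaker-minute and comparable to the per-speaker
  descriptives.
* **Proportions** (uhm choice, level-contour use) — per-speaker
  successes/totals with a binomial likelihood, logit link and a per-speaker
  random intercept; optionally a lexical-type effect and its interaction
  with group. Contrasts are reported in percentage points, as differences of
  population-level probabilities (random intercept at zero), because that is
  the scale on which the descriptive tables are read.
* **Scalars** (entropy, mean ΔST per speaker) — a Gaussian model on the
  standardized response, with the contrast mapped back to the raw scale.

Two engines produce the posterior draws. The MCMC engine (JAGS) uses
regularising weakly informative priors — normal(0, 2.5) coefficients,
half-normal scale parameters, an exponential prior on the NB shape — and by
default 4 chains × 4000 iterations with 2000 warm-up. The bootstrap engine
fits by maximum likelihood and generates draws by parametric bootstrap; it
is labelled distinctly in every output and is the pipeline default because
it runs in seconds at desk scale. Either way the reported numbers are
derived from the stored draws, so `p_delta_gt_0` is literally the share of
positive draws, and no significance labels are attached.

Identical data under swapped group labels mirror the contrast (δ → −δ,
p → 1 − p); degenerate designs (a single speaker per group, a group at
0%/100%, all-zero counts) run with a warning and a flag rather than
failing, since flagged output is more informative than an error halfway
through a pipeline.

## What the synthetic corpus emulates

`synth_config()` defaults encode the emulated study: 7 dyads per group
(ASD–ASD and CTR–CTR), one ~20-minute Map Task dialogue per dyad with
alternating turns (the instruction giver holding the floor somewhat longer),
filled pauses arriving as a homogeneous Poisson process within each
speaker's speech at 3.63 tokens per speaker-minute in both groups, uhm
probability .553 (ASD) / .600 (CTR), lognormal token durations targeting a
444 ms mean and 247 ms SD, and contour mixtures of
(rise, level, fall) = (.135, .553, .312) for ASD and (.073, .703, .224) for
CTR. The mixtures are the group-by-type proportions of the emulated corpus
aggregated across lexical types; they analytically reproduce pooled group
entropies of about 1.39 and 1.12 bits, so recovering those values end to end
is a genuine check of the whole chain.

Two defaults deserve their derivations:

* **Per-speaker rate jitter** (`speaker_rate_sd`, 1.32 ASD / 0.20 CTR).
  The emulated within-dyad rate differences (mean |r₁ − r₂| of 1.56 and
  0.53 tokens/min) are differences of *measured* rates, which carry Poisson
  counting noise on top of the latent speaker differences. For
  λᵢ ~ N(μ, σ²) and counts over T = 20 min, E|r̂₁ − r̂₂| =
  √(2/π) · √(2(σ² + μ/T)); solving for σ at μ = 3.63 gives the defaults.
  Using the naive folded-normal solution instead (ignoring counting noise)
  would overshoot the target differences.
* **Contour shape.** Contours are built in ST space around a speaker base
  F0 (120/220 Hz cycled over speakers) and exponentiated to Hz, flat over
  the first and last 10% of the token and linear in between. The plateau
  edges mean the nominal 10%/90% measurement points bracket exactly the
  programmed ΔST (+2.5 ST rises, −2.5 ST falls, N(0, 0.3 ST) level), so
  ground truth is exact by construction; fallback windows on
  dropout-affected tokens see a slightly attenuated ramp, which is the
  realistic behaviour. Multiplicative microprosodic noise (0.1 ST per
  0.01 s sample) and edge dropouts (probability 0.15, removing 10–30% of
  one edge) exercise the interpolation and fallback paths.

What the generator does **not** emulate: real lexical content, silent-pause
structure, overlap, turn-taking dynamics, role swapping across two tasks
(each synthetic speaker keeps one role; a `giver_rate_ratio` knob exists but
defaults to 1 so that role asymmetry does not contaminate the within-dyad
adaptation structure), complex rise-fall contours, and the long right tail
of annotation noise in human corpora. Passing recovery tests on this corpus
therefore shows the pipeline is correct and well-calibrated under its own
assumptions — not that any real population behaves this way.

## Numerical choices and degenerate inputs

* Times are seconds, half-open `[start, end)`, no frame quantization;
  written Praat files carry 15 significant digits, so round trips are exact
  far below the 1e-6 s documented tolerance.
* TextGrid/PitchTier parsing accepts the long and short text dialects in
  UTF-8 or UTF-16 (BOM-detected). Labels with Praat's doubled-quote escapes
  are handled; labels spanning physical lines are not (Praat does not wrap
  interval labels). Point tiers are skipped with a notice. Malformed files
  fail with the offending line named.
* An empty pitch tier is valid data (its tokens are excluded downstream
  with `empty_contour`); unsorted times or non-positive F0 are format
  errors.
* Label normalization is table-driven (case-insensitive, lengthening marks
  stripped); the default table covers the German forms plus common English
  spellings, with nasal-only "m"/"hm" counted as uhm. The table is an
  argument, not a constant, because annotation inventories vary by corpus.
* Proportion units with zero tokens are undefined and excluded, never
  imputed; `uhm_percentage()` and `contour_proportions()` raise errors on
  empty units so silent zeros cannot leak into group means.
* Entropy validates that proportions sum to 1 within 1e-9.
* The bootstrap rate engine falls back to a Poisson fit for bootstrap
  replicates in which the NB shape estimate diverges (a standard small-count
  pathology); draws are otherwise unfiltered.

## Problem sizes used by the test suite

The suite validates measurement exactness on constructed contours, the
fallback rule against an independent grid-scan oracle, generator
calibration at the full default corpus (~2000 tokens, ~9 speaker-hours),
and detection power with 50 replicate cohorts of 27 speakers × 37 tokens
fitted with the bootstrap engine at 100 draws. These sizes were chosen to
make Monte-Carlo error comfortably smaller than the margins being asserted
while keeping a full run in the minutes range; the MCMC engine is exercised
with short chains (2 × 1200) purely as a contract check, and its
full-length defaults are meant for real analyses.

## Known limitations

* The two-point summary cannot represent rise-fall or fall-rise contours;
  it is adequate only where contours are essentially monotone, which holds
  for short filled pauses but should be re-examined before applying the
  pipeline to longer interjections.
* The bootstrap engine's draws approximate a posterior under flat priors;
  for small or degenerate designs the MCMC engine with its regularising
  priors is the more trustworthy of the two.
* `read_corpus()` expects one dialogue per TextGrid and tier names equal to
  speaker ids; corpora organised differently need a thin adapter before the
  pipeline.
* Binary Praat formats are out of scope; export to the text dialects first.
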