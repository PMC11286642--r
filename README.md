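# hesitone

Quantifying the prosody of filled pauses ("äh"/"ähm", "uh"/"uhm") in dyadic
conversation, and comparing groups of speakers.

## The problem

Filled pauses are normally produced with a flat intonation contour. Whether
a group of speakers — for instance autistic adults in conversation with each
other, compared with non-autistic dyads — departs from that convention is a
question about *prosodic realisation*, not about how often or which filled
pauses are produced. Answering it requires a chain of small, well-defined
steps: finding the tokens in time-aligned annotations, measuring each
token's pitch movement robustly in the presence of unvoiced stretches,
categorising the movement, and comparing groups with models that respect the
nested structure (tokens within speakers within dyads). `hesitone`
implements that chain for anyone working with Praat-style annotation and
pitch files: clinical speech researchers, phoneticians, and conversation
analysts.

## The measurements

For a token spanning `[t0, t1]` with F0 track `f(t)`, the pitch movement is

    ΔST = 12 · log2( f(t0 + 0.9·d) / f(t0 + 0.1·d) ),   d = t1 − t0

i.e. the semitone difference between the points at 10% and 90% of token
duration (edges avoided because of microprosody and glottalization). If F0
is undefined at a nominal point it moves inward in 10% steps — to at most
40% at the start and 70% at the end, each edge independently; tokens with no
usable window are excluded with the reason recorded. Movements within ±1 ST
are **level**, beyond the band **rise** (positive) or **fall** (negative).
Per speaker, contour diversity is Shannon entropy over the three category
proportions, `H = −Σ p·log2 p ∈ [0, log2 3 ≈ 1.58]`.

Speakers and dyads are summarised by tokens per speaker-minute, uhm
percentage, duration-based filled-pause proportions by conversational role,
and the absolute within-dyad rate difference (an adaptation index). Group
contrasts come from three Bayesian model structures — negative-binomial
counts with exposure offset, hierarchical binomial proportions with speaker
random intercepts (optionally group × lexical-type), Gaussian scalars — each
reporting the posterior mean difference δ, its 95% credible interval, and
P(δ > 0), via MCMC (JAGS) or a fast ML + parametric-bootstrap engine.

A synthetic-corpus generator with exact ground truth (programmed rates,
mixtures, slopes, noise, and edge dropouts) backs every stage with
recoverable targets; see the vignette in `vignettes/` for the model,
parameter and calibration details.

## Worked example

```r
library(hesitone)

cfg    <- synth_config(n_dyads_per_group = 3, dialogue_minutes = 10, seed = 42)
corpus <- generate_corpus(cfg)                   # TextGrids + PitchTiers + truth
report <- run_pipeline(corpus, model_method = "bootstrap",
                       n_boot = 300, seed = 1)

report$counters
#> $n_extracted
#> [1] 443
#> $n_analyzed
#> [1] 439
#> $n_excluded
#> [1] 4

report$descriptives[, c("group", "rate_pooled", "within_dyad_diff_mean",
                        "uhm_pct_pooled")]
#>   group rate_pooled within_dyad_diff_mean uhm_pct_pooled
#> 1   ASD        3.98                 0.967           59.0
#> 2   CTR        3.40                 0.200           60.8

report$models$level
#> pct: CTR - ASD: mean delta = 18.235, 95% CI [10.100, 27.056],
#>   P(delta>0) = 1.000 (bootstrap, 300 draws)
```

Reading the output: of 443 extracted tokens, 4 had no usable pitch window
and were excluded. Both groups hesitate at a similar rate (~3.4–4.0 tokens
per speaker-minute) and prefer uhm (~60%), but control dyads converge more
within dyads (mean rate difference 0.20 vs 0.97 tokens/min), and the level
model finds control speakers about 18 percentage points more likely to
produce the canonical level contour — the programmed group difference of
this synthetic corpus (70.3% vs 55.3% level), recovered with an interval
well clear of zero.

`write_corpus(corpus, dir)` / `read_corpus(dir)` round-trip everything
through the standard on-disk formats, and
`inst/scripts/hesitone-cli.R` wraps `simulate` and `run` for shell use.

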