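Package: hesitone
Title: Prosodic Analysis of Filled Pauses in Dyadic Conversation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantifying filled-pause ("uh"/"uhm", German
    "aeh"/"aehm") production and prosody in time-aligned dyadic conversation.
    Reads Praat TextGrid annotations and PitchTier fundamental-frequency
    tracks, normalises hesitation labels into a token table, measures each
    token's intonation as the semitone difference between near-edge pitch
    points (10 and 90 percent of token duration, with an inward fallback when
    pitch is undefined), classifies contours as rise, level or fall, and
    summarises speakers and dyads by rate per minute, lexical-type preference,
    role-based duration proportions and Shannon entropy of contour use.
    Group contrasts are estimated with Bayesian negative-binomial, hierarchical
    binomial and Gaussian models (MCMC via JAGS, with a maximum-likelihood
    plus parametric-bootstrap alternative), reporting posterior means, 95
    percent credible intervals and the posterior probability of a positive
    difference. A synthetic-corpus generator with known ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    MASS,
    lme4,
    stats,
    utils
Suggests:
    rjags,
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
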