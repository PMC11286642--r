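# Synthetic dyadic corpora with known ground truth. The generator emulates
# the study conditions of a disposition-matched Map Task corpus: 7 dyads per
# group (ASD-ASD and CTR-CTR), ~20 minutes of task dialogue per dyad, filled
# pauses arriving as a Poisson process inside each speaker's speech turns at
# 3.63 tokens/minute, lexical choice Bernoulli (uhm probability .553 ASD /
# .600 CTR), lognormal token durations targeting mean 444 ms / SD 247 ms,
# and per-token pitch contours built in semitone space around a speaker base
# F0 so the programmed end-minus-start difference is exact by construction.
# Per-speaker rate jitter (SD 1.38 ASD / 0.47 CTR) reproduces the observed
# difference in within-dyad adaptation. Optional edge dropouts emulate the
# non-modal stretches that trigger the measurement fallback rule.

#' Configuration for the synthetic-corpus generator
#'
#' All probabilities are per token, all rates per minute, durations in ms.
#' Defaults encode the emulated study conditions; see the package vignette
#' for the reasoning behind each value.
#'
#' @param n_dyads_per_group Dyads per group (two speakers each).
#' @param dialogue_minutes Dialogue duration per dyad, minutes.
#' @param rate_per_min Named vector `c(ASD = , CTR = )`: group mean
#'   filled-pause rates.
#' @param speaker_rate_sd Named vector: SD of per-speaker rate jitter around
#'   the group mean (controls within-dyad differences); speaker rates are
#'   truncated below at 0.3/min. The defaults are solved so that the expected
#'   absolute difference of *measured* partner rates (which adds Poisson
#'   counting noise to the latent jitter) matches the emulated conditions;
#'   see the vignette.
#' @param giver_rate_ratio Multiplicative rate asymmetry between roles: the
#'   giver's rate is scaled by its square root and the follower's by its
#'   inverse square root, keeping the dyad mean. Default 1 (no asymmetry).
#' @param uhm_prob Named vector: probability that a token is uhm.
#' @param contour_mix Named list of length-3 vectors `(rise, level, fall)`
#'   per group, each summing to 1.
#' @param slope_st Programmed absolute semitone change for rises and falls.
#' @param level_jitter_st SD of the programmed change for level tokens.
#' @param duration_mean_ms,duration_sd_ms Target mean and SD of the lognormal
#'   token-duration distribution.
#' @param noise_st SD of per-sample microprosodic noise, semitones.
#' @param dropout_prob Probability that a token has one unvoiced edge region.
#' @param dropout_frac_range Range of the dropped fraction of token duration.
#' @param f0_base_hz Base F0 values cycled over speakers.
#' @param pitch_dt Pitch sampling step, seconds.
#' @param seed Integer seed; the whole corpus is deterministic given it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_dyads_per_group = 7L,
                         dialogue_minutes = 20,
                         rate_per_min = c(ASD = 3.63, CTR = 3.63),
                         speaker_rate_sd = c(ASD = 1.32, CTR = 0.20),
                         giver_rate_ratio = 1,
                         uhm_prob = c(ASD = 0.553, CTR = 0.600),
                         contour_mix = list(
                           ASD = c(rise = 0.135, level = 0.553, fall = 0.312),
                           CTR = c(rise = 0.073, level = 0.703, fall = 0.224)
                         ),
                         slope_st = 2.5,
                         level_jitter_st = 0.3,
                         duration_mean_ms = 444,
                         duration_sd_ms = 247,
                         noise_st = 0.1,
                         dropout_prob = 0.15,
                         dropout_frac_range = c(0.10, 0.30),
                         f0_base_hz = c(120, 220),
                         pitch_dt = 0.01,
                         seed = 1L) {
  cfg <- list(
    n_dyads_per_group = as.integer(n_dyads_per_group),
    dialogue_minutes = dialogue_minutes,
    rate_per_min = rate_per_min,
    speaker_rate_sd = speaker_rate_sd,
    giver_rate_ratio = giver_rate_ratio,
    uhm_prob = uhm_prob,
    contour_mix = contour_mix,
    slope_st = slope_st,
    level_jitter_st = level_jitter_st,
    duration_mean_ms = duration_mean_ms,
    duration_sd_ms = duration_sd_ms,
    noise_st = noise_st,
    dropout_prob = dropout_prob,
    dropout_frac_range = dropout_frac_range,
    f0_base_hz = f0_base_hz,
    pitch_dt = pitch_dt,
    seed = as.integer(seed)
  )
  for (g in c("ASD", "CTR")) {
    if (is.na(cfg$rate_per_min[g]) || is.na(cfg$uhm_prob[g])) {
      stop("rate_per_min and uhm_prob need named entries for ASD and CTR",
        call. = FALSE
      )
    }
    mix <- cfg$contour_mix[[g]]
    if (length(mix) != 3L || abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
      stop("contour_mix$", g, " must be 3 non-negative values summing to 1",
        call. = FALSE
      )
    }
  }
  stopifnot(
    cfg$n_dyads_per_group >= 1L,
    cfg$dialogue_minutes > 0,
    all(cfg$rate_per_min > 0),
    all(cfg$speaker_rate_sd >= 0),
    cfg$giver_rate_ratio > 0,
    all(cfg$uhm_prob >= 0 & cfg$uhm_prob <= 1),
    cfg$slope_st > 0, cfg$level_jitter_st >= 0,
    cfg$duration_mean_ms > 0, cfg$duration_sd_ms > 0,
    cfg$noise_st >= 0,
    cfg$dropout_prob >= 0 && cfg$dropout_prob <= 1,
    cfg$pitch_dt > 0
  )
  structure(cfg, class = "synth_config")
}

# lognormal parameters hitting a target mean and SD
lognormal_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one token's pitch contour
#'
#' A monotone semitone trajectory from the speaker's base F0 with the
#' programmed end-minus-start change (`+slope_st` for a rise, `-slope_st` for
#' a fall, a small normal jitter for level): flat over the first and last 10%
#' of the token and linear in between, so the nominal 10%/90% measurement
#' points bracket exactly the programmed change. Sampled every `pitch_dt`
#' seconds, with multiplicative microprosodic noise and an optional unvoiced
#' edge region.
#'
#' @param category `"rise"`, `"level"` or `"fall"`.
#' @param config A [synth_config()].
#' @param f0_base_hz Speaker base F0.
#' @param start_s,end_s Token span, seconds.
#' @param dropout One of `"none"`, `"start"`, `"end"`: which edge, if any,
#'   loses its samples.
#' @param dropout_frac Fraction of token duration removed at that edge.
#' @return A list with `samples` (tibble `time_s`, `f0_hz`), `delta_st_true`,
#'   `dropout`, `dropout_frac`.
#' @export
generate_token_contour <- function(category, config, f0_base_hz = 120,
                                   start_s = 0, end_s = start_s + 0.444,
                                   dropout = c("none", "start", "end"),
                                   dropout_frac = 0.2) {
  category <- match.arg(category, contour_levels())
  dropout <- match.arg(dropout)
  dur <- end_s - start_s
  stopifnot(dur > 0)

  delta <- switch(category,
    rise = config$slope_st,
    fall = -config$slope_st,
    level = stats::rnorm(1, 0, config$level_jitter_st)
  )
  t <- seq(start_s, end_s, by = config$pitch_dt)
  st0 <- hz_to_st(f0_base_hz)
  ramp <- pmin(pmax(((t - start_s) / dur - 0.1) / 0.8, 0), 1)
  st <- st0 + ramp * delta
  if (config$noise_st > 0) {
    st <- st + stats::rnorm(length(t), 0, config$noise_st)
  }
  keep <- rep(TRUE, length(t))
  if (dropout == "start") {
    keep <- t >= start_s + dropout_frac * dur
  } else if (dropout == "end") {
    keep <- t <= end_s - dropout_frac * dur
  }
  list(
    samples = tibble::tibble(time_s = t[keep], f0_hz = 2^(st[keep] / 12)),
    delta_st_true = delta,
    dropout = dropout,
    dropout_frac = if (dropout == "none") 0 else dropout_frac
  )
}

# Alternating speech turns for the two speakers of a dyad. The giver holds
# the floor longer on average, so role-based duration proportions have
# something to measure.
make_turns <- function(total_s, mean_turn_s = c(6, 4)) {
  turns <- list(list(), list())
  t <- 0
  who <- 1L
  while (t < total_s - 1) {
    len <- stats::rexp(1, 1 / mean_turn_s[who]) + 0.8
    len <- min(len, total_s - t)
    turns[[who]][[length(turns[[who]]) + 1L]] <- c(t, t + len)
    t <- t + len + stats::runif(1, 0.2, 0.8)
    who <- 3L - who
  }
  lapply(turns, function(x) {
    m <- do.call(rbind, x)
    tibble::tibble(start_s = m[, 1], end_s = m[, 2])
  })
}

place_tokens <- function(n, turns, durations_s, min_gap = 0.05) {
  if (n == 0L) {
    return(numeric(0))
  }
  lens <- turns$end_s - turns$start_s
  placed_start <- numeric(0)
  placed_end <- numeric(0)
  onsets <- numeric(n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(200L)) {
      i <- sample.int(nrow(turns), 1L, prob = lens)
      on <- stats::runif(1, turns$start_s[i], turns$end_s[i])
      off <- on + durations_s[k]
      if (off > turns$end_s[i]) next
      if (any(on < placed_end + min_gap & off > placed_start - min_gap)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(
        "could not place token ", k, " of ", n,
        ": filled-pause rate too high for the available speech time; ",
        "lower the rate or lengthen the dialogue",
        call. = FALSE
      )
    }
    placed_start <- c(placed_start, on)
    placed_end <- c(placed_end, off)
    onsets[k] <- on
  }
  onsets
}

# tier = speech turns with token intervals cut out and labelled
build_tier <- function(turns, tok_start, tok_end, tok_label, total_s) {
  pieces <- list()
  for (i in seq_len(nrow(turns))) {
    a <- turns$start_s[i]
    b <- turns$end_s[i]
    inside <- which(tok_start >= a - 1e-9 & tok_end <= b + 1e-9)
    inside <- inside[order(tok_start[inside])]
    cur <- a
    for (j in inside) {
      if (tok_start[j] > cur + 1e-9) {
        pieces[[length(pieces) + 1L]] <- c(cur, tok_start[j], NA)
      }
      pieces[[length(pieces) + 1L]] <- c(tok_start[j], tok_end[j], j)
      cur <- tok_end[j]
    }
    if (b > cur + 1e-9) {
      pieces[[length(pieces) + 1L]] <- c(cur, b, NA)
    }
  }
  m <- do.call(rbind, pieces)
  lab <- ifelse(is.na(m[, 3]), "speech", tok_label[m[, 3]])
  tier <- tibble::tibble(start_s = m[, 1], end_s = m[, 2], label = lab)
  # fill silences so the tier covers [0, total_s] like a Praat tier
  filled <- list()
  cur <- 0
  for (i in seq_len(nrow(tier))) {
    if (tier$start_s[i] > cur + 1e-9) {
      filled[[length(filled) + 1L]] <-
        tibble::tibble(start_s = cur, end_s = tier$start_s[i], label = "")
    }
    filled[[length(filled) + 1L]] <- tier[i, ]
    cur <- tier$end_s[i]
  }
  if (total_s > cur + 1e-9) {
    filled[[length(filled) + 1L]] <-
      tibble::tibble(start_s = cur, end_s = total_s, label = "")
  }
  dplyr::bind_rows(filled)
}

#' Generate a synthetic dyadic corpus
#'
#' Produces annotations ([`textgrid`][read_textgrid()] objects), per-speaker
#' pitch tracks, speaker metadata and full ground truth, deterministically
#' given `config$seed`. With `dir` set, everything is also written to disk in
#' the same formats the readers consume (one `.TextGrid` per dyad, one
#' `.PitchTier` per speaker, `metadata.csv`, `ground_truth_tokens.csv`,
#' `ground_truth_speakers.csv`).
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory (created if needed).
#' @return An object of class `fp_corpus`: a list with `config`,
#'   `annotations` (list of textgrids), `pitch` (named list of pitchtiers),
#'   `metadata`, and `ground_truth` (list with `tokens` and `speakers`
#'   tibbles).
#' @export
generate_corpus <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  total_s <- config$dialogue_minutes * 60
  dpar <- lognormal_pars(config$duration_mean_ms, config$duration_sd_ms)

  annotations <- list()
  pitch <- list()
  meta_rows <- list()
  gt_tokens <- list()
  gt_speakers <- list()
  spk_counter <- 0L

  for (grp in c("ASD", "CTR")) {
    for (d in seq_len(config$n_dyads_per_group)) {
      dyad_id <- sprintf("%s%02d", grp, d)
      turns <- make_turns(total_s)
      tiers <- list()

      for (w in 1:2) {
        spk_counter <- spk_counter + 1L
        speaker_id <- sprintf("%s_%s", dyad_id, c("A", "B")[w])
        role <- c("giver", "follower")[w]
        f0_base <- config$f0_base_hz[(spk_counter - 1L) %%
          length(config$f0_base_hz) + 1L]

        role_adj <- if (role == "giver") {
          sqrt(config$giver_rate_ratio)
        } else {
          1 / sqrt(config$giver_rate_ratio)
        }
        lambda <- role_adj * max(
          0.3,
          stats::rnorm(1, config$rate_per_min[grp], config$speaker_rate_sd[grp])
        )
        n_tok <- stats::rpois(1, lambda * config$dialogue_minutes)
        dur_s <- stats::rlnorm(n_tok, dpar$meanlog, dpar$sdlog) / 1000
        onsets <- place_tokens(n_tok, turns[[w]], dur_s)
        ord <- order(onsets)
        onsets <- onsets[ord]
        dur_s <- dur_s[ord]

        is_uhm <- stats::rbinom(max(n_tok, 0L), 1, config$uhm_prob[grp]) == 1
        label <- ifelse(is_uhm, "\u00e4hm", "\u00e4h")
        category <- sample(
          contour_levels(), n_tok,
          replace = TRUE, prob = config$contour_mix[[grp]]
        )

        samples <- list()
        tok_gt <- vector("list", n_tok)
        for (k in seq_len(n_tok)) {
          drop_edge <- "none"
          drop_frac <- 0
          if (stats::runif(1) < config$dropout_prob) {
            drop_edge <- sample(c("start", "end"), 1L)
            drop_frac <- stats::runif(
              1, config$dropout_frac_range[1], config$dropout_frac_range[2]
            )
          }
          ctr <- generate_token_contour(
            category[k], config,
            f0_base_hz = f0_base,
            start_s = onsets[k], end_s = onsets[k] + dur_s[k],
            dropout = drop_edge, dropout_frac = drop_frac
          )
          samples[[k]] <- ctr$samples
          tok_gt[[k]] <- tibble::tibble(
            token_id = sprintf("%s_%s_%03d", dyad_id, speaker_id, k),
            dialogue_id = dyad_id,
            speaker_id = speaker_id,
            dyad_id = dyad_id,
            group = grp,
            role = role,
            lexical_type = ifelse(is_uhm[k], "uhm", "uh"),
            category = category[k],
            delta_st_true = ctr$delta_st_true,
            start_s = onsets[k],
            end_s = onsets[k] + dur_s[k],
            duration_ms = dur_s[k] * 1000,
            dropout = ctr$dropout,
            dropout_frac = ctr$dropout_frac
          )
        }

        pt_samples <- if (n_tok > 0L) {
          dplyr::arrange(dplyr::bind_rows(samples), .data$time_s)
        } else {
          tibble::tibble(time_s = numeric(0), f0_hz = numeric(0))
        }
        pitch[[speaker_id]] <- new_pitchtier(speaker_id, 0, total_s, pt_samples)
        tiers[[speaker_id]] <- build_tier(
          turns[[w]], onsets, onsets + dur_s, label, total_s
        )

        meta_rows[[spk_counter]] <- tibble::tibble(
          speaker_id = speaker_id, dyad_id = dyad_id,
          group = grp, role = role
        )
        gt_speakers[[spk_counter]] <- tibble::tibble(
          speaker_id = speaker_id, dyad_id = dyad_id, group = grp, role = role,
          true_rate_per_min = lambda,
          true_uhm_prob = unname(config$uhm_prob[grp]),
          true_p_rise = config$contour_mix[[grp]][["rise"]],
          true_p_level = config$contour_mix[[grp]][["level"]],
          true_p_fall = config$contour_mix[[grp]][["fall"]],
          f0_base_hz = f0_base,
          n_tokens = n_tok
        )
        gt_tokens[[length(gt_tokens) + 1L]] <- dplyr::bind_rows(tok_gt)
      }

      annotations[[dyad_id]] <- structure(
        list(dialogue_id = dyad_id, xmin = 0, xmax = total_s, tiers = tiers),
        class = "textgrid"
      )
    }
  }

  corpus <- structure(
    list(
      config = config,
      annotations = annotations,
      pitch = pitch,
      metadata = dplyr::bind_rows(meta_rows),
      ground_truth = list(
        tokens = dplyr::bind_rows(gt_tokens),
        speakers = dplyr::bind_rows(gt_speakers)
      )
    ),
    class = "fp_corpus"
  )
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

#' Write a synthetic corpus to disk
#'
#' @param corpus An `fp_corpus`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "fp_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tg in corpus$annotations) {
    write_textgrid(tg, file.path(dir, paste0(tg$dialogue_id, ".TextGrid")))
  }
  for (pt in corpus$pitch) {
    write_pitchtier(pt, file.path(dir, paste0(pt$speaker_id, ".PitchTier")))
  }
  utils::write.csv(corpus$metadata, file.path(dir, "metadata.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  utils::write.csv(
    corpus$ground_truth$tokens,
    file.path(dir, "ground_truth_tokens.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  utils::write.csv(
    corpus$ground_truth$speakers,
    file.path(dir, "ground_truth_speakers.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(dir)
}

#' Read a corpus directory
#'
#' Reads every `.TextGrid` and `.PitchTier` in `dir` plus `metadata.csv`
#' (and ground-truth tables when present, e.g. for corpora written by
#' [write_corpus()]).
#'
#' @param dir Directory with annotation, pitch and metadata files.
#' @return An `fp_corpus` (with `config = NULL` for externally produced
#'   data).
#' @export
read_corpus <- function(dir) {
  tg_files <- list.files(dir, pattern = "\\.[Tt]ext[Gg]rid$", full.names = TRUE)
  pt_files <- list.files(dir, pattern = "\\.[Pp]itch[Tt]ier$", full.names = TRUE)
  meta_file <- file.path(dir, "metadata.csv")
  if (length(tg_files) == 0L || !file.exists(meta_file)) {
    stop("corpus directory needs at least one .TextGrid and a metadata.csv",
      call. = FALSE
    )
  }
  annotations <- lapply(tg_files, read_textgrid)
  names(annotations) <- vapply(annotations, function(x) x$dialogue_id, "")
  pitch <- lapply(pt_files, read_pitchtier)
  names(pitch) <- vapply(pitch, function(x) x$speaker_id, "")
  metadata <- tibble::as_tibble(utils::read.csv(
    meta_file,
    stringsAsFactors = FALSE, fileEncoding = "UTF-8"
  ))
  gt <- NULL
  gt_tok <- file.path(dir, "ground_truth_tokens.csv")
  gt_spk <- file.path(dir, "ground_truth_speakers.csv")
  if (file.exists(gt_tok) && file.exists(gt_spk)) {
    gt <- list(
      tokens = tibble::as_tibble(
        utils::read.csv(gt_tok, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
      ),
      speakers = tibble::as_tibble(
        utils::read.csv(gt_spk, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
      )
    )
  }
  structure(
    list(
      config = NULL, annotations = annotations, pitch = pitch,
      metadata = metadata, ground_truth = gt
    ),
    class = "fp_corpus"
  )
}

#' @export
print.fp_corpus <- function(x, ...) {
  cat(
    "<fp_corpus>", length(x$annotations), "dialogue(s),",
    nrow(x$metadata), "speakers",
    if (!is.null(x$ground_truth)) {
      paste0("(", nrow(x$ground_truth$tokens), " ground-truth tokens)")
    } else {
      "(no ground truth)"
    }, "\n"
  )
  invisible(x)
}
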