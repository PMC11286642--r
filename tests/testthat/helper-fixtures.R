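# In-code fixture builders shared across the suite.

# a pitch contour from explicit samples
make_pt <- function(time_s, f0_hz, speaker_id = "S1", xmin = 0,
                    xmax = max(time_s, 1)) {
  hesitone:::new_pitchtier(
    speaker_id, xmin, xmax,
    tibble::tibble(time_s = time_s, f0_hz = f0_hz)
  )
}

# a dense contour over a token span with given endpoint semitone change and
# optional edge gaps (fractions of the span removed at start/end)
make_token_contour <- function(start_s = 0, end_s = 0.5, f0_start = 120,
                               delta_st = 0, drop_start = 0, drop_end = 0,
                               dt = 0.005, speaker_id = "S1") {
  t <- seq(start_s, end_s, by = dt)
  frac <- (t - start_s) / (end_s - start_s)
  st <- hz_to_st(f0_start) + frac * delta_st
  keep <- frac >= drop_start - 1e-12 & frac <= 1 - drop_end + 1e-12
  make_pt(t[keep], 2^(st[keep] / 12),
    speaker_id = speaker_id, xmin = start_s, xmax = end_s
  )
}

# one-tier textgrid from vectors
make_tg <- function(start_s, end_s, label, speaker = "S1",
                    dialogue_id = "dlg", xmax = max(end_s)) {
  structure(
    list(
      dialogue_id = dialogue_id, xmin = 0, xmax = xmax,
      tiers = stats::setNames(
        list(tibble::tibble(start_s = start_s, end_s = end_s, label = label)),
        speaker
      )
    ),
    class = "textgrid"
  )
}

make_meta <- function(speaker_id = "S1", dyad_id = "D1", group = "ASD",
                      role = "giver") {
  tibble::tibble(
    speaker_id = speaker_id, dyad_id = dyad_id, group = group, role = role
  )
}

# tiny fast synthetic corpus for pipeline-level tests
tiny_corpus <- function(seed = 11, n_dyads = 2, minutes = 4, ...) {
  generate_corpus(synth_config(
    n_dyads_per_group = n_dyads, dialogue_minutes = minutes, seed = seed, ...
  ))
}

# independent oracle for the fallback rule: scan the fraction grids and pick
# the first fraction at which the raw samples can support a value (a sample
# within max_gap on both sides, or an exact hit)
oracle_fracs <- function(contour, start_s, end_s, max_gap = 0.02) {
  defined_at <- function(t) {
    ts <- contour$samples$time_s
    if (any(abs(ts - t) < 1e-12)) return(TRUE)
    lo <- max(c(-Inf, ts[ts < t]))
    hi <- min(c(Inf, ts[ts > t]))
    is.finite(lo) && is.finite(hi) && (hi - lo) <= max_gap
  }
  dur <- end_s - start_s
  s <- Filter(function(fr) defined_at(start_s + fr * dur), c(.1, .2, .3, .4))
  e <- Filter(function(fr) defined_at(start_s + fr * dur), c(.9, .8, .7))
  if (length(s) == 0L || length(e) == 0L) {
    return(NULL)
  }
  c(start_frac = s[[1]], end_frac = e[[1]])
}
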