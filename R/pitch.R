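# Near-edge pitch measurement. Each token's intonation is summarised by the
# semitone difference between an early and a late pitch point, nominally at
# 10% and 90% of token duration -- inside the edges so that microprosody and
# glottalization at syllable boundaries are avoided. When F0 is undefined at
# a nominal point (non-modal voice, unvoiced stretch), that edge's point is
# moved inward in 10% steps, to at most 40% at the start and 70% at the end.
# Tokens for which no defined pair exists are excluded, with the reason
# recorded.

#' Convert frequency to semitones
#'
#' `12 * log2(f / ref)`; the default reference of 1 Hz makes absolute values
#' reportable, and cancels in differences.
#'
#' @param f Frequency in Hz (vectorized), must be positive.
#' @param ref Reference frequency in Hz, must be positive.
#' @return Semitones relative to `ref`.
#' @examples
#' hz_to_st(1)                      # 0
#' hz_to_st(200) - hz_to_st(100)    # 12 (one octave)
#' @export
hz_to_st <- function(f, ref = 1) {
  if (length(ref) != 1L || !is.finite(ref) || ref <= 0) {
    stop("`ref` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("frequencies must be positive and finite", call. = FALSE)
  }
  12 * log2(f / ref)
}

#' Sample F0 from a pitch contour at arbitrary times
#'
#' Linear interpolation between adjacent samples, restricted to voiced runs:
#' a query time yields a value only if it coincides with a sample or falls
#' between two samples closer than `max_gap` seconds. Everywhere else
#' (before the first sample, after the last, or inside a wider gap) F0 is
#' undefined and `NA` is returned — undefined is a value, not an error.
#'
#' @param contour A `pitchtier`.
#' @param t Numeric vector of query times in seconds.
#' @param max_gap Maximum spacing (s) between samples still treated as one
#'   voiced run. Default 0.02 s, i.e. two standard Praat pitch frames.
#' @return Numeric vector of F0 in Hz, `NA` where undefined.
#' @export
sample_f0 <- function(contour, t, max_gap = 0.02) {
  stopifnot(inherits(contour, "pitchtier"))
  times <- contour$samples$time_s
  f0 <- contour$samples$f0_hz
  n <- length(times)
  out <- rep(NA_real_, length(t))
  if (n == 0L) return(out)

  idx <- findInterval(t, times)
  for (k in seq_along(t)) {
    i <- idx[k]
    if (i >= 1L && times[i] == t[k]) {
      out[k] <- f0[i]
    } else if (i >= 1L && i < n) {
      gap <- times[i + 1L] - times[i]
      if (gap <= max_gap) {
        w <- (t[k] - times[i]) / gap
        out[k] <- (1 - w) * f0[i] + w * f0[i + 1L]
      }
    }
  }
  out
}

#' Median-smooth a pitch contour
#'
#' Optional 3-point (or wider odd-k) running-median pre-smoothing, a light
#' automated stand-in for hand-corrected contours. Off by default throughout
#' the pipeline.
#'
#' @param contour A `pitchtier`.
#' @param k Odd window width, default 3.
#' @return A `pitchtier` with smoothed `f0_hz`.
#' @export
smooth_contour <- function(contour, k = 3L) {
  stopifnot(inherits(contour, "pitchtier"))
  s <- contour$samples
  if (nrow(s) >= k) {
    s$f0_hz <- as.numeric(stats::runmed(s$f0_hz, k, endrule = "median"))
  }
  new_pitchtier(contour$speaker_id, contour$xmin, contour$xmax, s)
}

start_fracs <- function() c(0.10, 0.20, 0.30, 0.40)
end_fracs <- function() c(0.90, 0.80, 0.70)

#' Select measurement points for one token
#'
#' Starts from the 10%/90% points of the token span. Each edge moves inward
#' independently, in steps of 10% of token duration, only while its F0 is
#' undefined (start: at most 40%; end: at most 70%). If either edge exhausts
#' its range without finding a defined value the token is excluded.
#'
#' @param contour A `pitchtier` for the token's speaker.
#' @param start_s,end_s Token span in seconds; `end_s > start_s`.
#' @param token_id Identifier carried into the result.
#' @param max_gap Voiced-run gap tolerance passed to [sample_f0()].
#' @return A one-row tibble. On success: `token_id`, `start_frac`,
#'   `end_frac`, `f_start_hz`, `f_end_hz`, `delta_st` and `excluded = FALSE`.
#'   On failure: `excluded = TRUE` and `reason` (`"empty_contour"` or
#'   `"no_pitch_at_any_window"`), measurement columns `NA`.
#' @export
select_points <- function(contour, start_s, end_s, token_id = NA_character_,
                          max_gap = 0.02) {
  stopifnot(inherits(contour, "pitchtier"))
  dur <- end_s - start_s
  if (!is.finite(dur) || dur <= 0) {
    stop("degenerate token: duration must be positive", call. = FALSE)
  }

  if (nrow(contour$samples) == 0L) {
    return(measurement_row(token_id, reason = "empty_contour"))
  }

  f_at <- function(frac) sample_f0(contour, start_s + frac * dur, max_gap)

  pick <- function(fracs) {
    for (fr in fracs) {
      f <- f_at(fr)
      if (!is.na(f)) return(c(fr, f))
    }
    NULL
  }

  a <- pick(start_fracs())
  b <- pick(end_fracs())
  if (is.null(a) || is.null(b)) {
    return(measurement_row(token_id, reason = "no_pitch_at_any_window"))
  }

  measurement_row(
    token_id,
    start_frac = a[1], end_frac = b[1],
    f_start_hz = a[2], f_end_hz = b[2],
    delta_st = hz_to_st(b[2]) - hz_to_st(a[2])
  )
}

measurement_row <- function(token_id, start_frac = NA_real_,
                            end_frac = NA_real_, f_start_hz = NA_real_,
                            f_end_hz = NA_real_, delta_st = NA_real_,
                            reason = NA_character_) {
  tibble::tibble(
    token_id = token_id,
    start_frac = start_frac, end_frac = end_frac,
    f_start_hz = f_start_hz, f_end_hz = f_end_hz,
    delta_st = delta_st,
    excluded = !is.na(reason),
    reason = reason
  )
}

#' Measure all tokens against their speakers' pitch contours
#'
#' Applies [select_points()] to every token. Every token yields exactly one
#' row in either the measurement or the exclusion table.
#'
#' @param tokens Token table from [extract_tokens()].
#' @param pitch Named list of `pitchtier` objects, keyed by `speaker_id`.
#' @param max_gap Voiced-run gap tolerance in seconds.
#' @param smooth If `TRUE`, apply [smooth_contour()] before measuring.
#' @param flag_implausible If `TRUE`, move tokens with `|delta_st| > 12`
#'   within less than 100 ms to the exclusion table as `user_flagged`
#'   (an automated plausibility screen; off by default).
#' @return A list with `measurements` (columns `token_id`, `start_frac`,
#'   `end_frac`, `f_start_hz`, `f_end_hz`, `delta_st`) and `exclusions`
#'   (`token_id`, `reason`).
#' @export
measure_tokens <- function(tokens, pitch, max_gap = 0.02, smooth = FALSE,
                           flag_implausible = FALSE) {
  missing <- setdiff(unique(tokens$speaker_id), names(pitch))
  if (length(missing) > 0L) {
    stop("no pitch contour for speaker(s): ",
      paste(sort(missing), collapse = ", "),
      call. = FALSE
    )
  }
  if (smooth) pitch <- lapply(pitch, smooth_contour)

  rows <- vector("list", nrow(tokens))
  for (i in seq_len(nrow(tokens))) {
    rows[[i]] <- select_points(
      pitch[[tokens$speaker_id[i]]],
      tokens$start_s[i], tokens$end_s[i],
      token_id = tokens$token_id[i],
      max_gap = max_gap
    )
  }
  res <- dplyr::bind_rows(rows)

  if (flag_implausible && nrow(res) > 0L) {
    dur_ms <- tokens$duration_ms[match(res$token_id, tokens$token_id)]
    bad <- !res$excluded & abs(res$delta_st) > 12 & dur_ms < 100
    res$excluded[bad] <- TRUE
    res$reason[bad] <- "user_flagged"
  }

  list(
    measurements = dplyr::select(
      res[!res$excluded, ],
      "token_id", "start_frac", "end_frac",
      "f_start_hz", "f_end_hz", "delta_st"
    ),
    exclusions = dplyr::select(res[res$excluded, ], "token_id", "reason")
  )
}
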