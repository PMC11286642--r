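# Distributional metrics per speaker and dyad: filled-pause rate per minute
# of dialogue, lexical-type preference (% uhm), duration-based proportions by
# speaker role, and the within-dyad rate difference used as an adaptation
# index.

#' Filled-pause rate per minute
#'
#' @param n_tokens Token count(s).
#' @param duration_s Dialogue duration(s) in seconds, positive.
#' @return Tokens per minute: `60 * n_tokens / duration_s`.
#' @examples
#' rate_per_minute(10, 300) # 2
#' @export
rate_per_minute <- function(n_tokens, duration_s) {
  if (any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  if (any(n_tokens < 0)) {
    stop("`n_tokens` must be non-negative", call. = FALSE)
  }
  60 * n_tokens / duration_s
}

#' Within-dyad rate difference
#'
#' Absolute difference of the two partners' filled-pause rates; smaller
#' values indicate stronger mutual adaptation.
#'
#' @param rate_a,rate_b Rates (tokens/minute) of the two speakers of a dyad.
#' @return `|rate_a - rate_b|`.
#' @export
within_dyad_difference <- function(rate_a, rate_b) {
  abs(rate_a - rate_b)
}

#' Percentage of uhm among a unit's tokens
#'
#' @param n_uhm Number of uhm tokens.
#' @param n_tokens Total token count; must be at least 1 (units without
#'   tokens are excluded from lexical-choice analyses).
#' @return `100 * n_uhm / n_tokens`.
#' @export
uhm_percentage <- function(n_uhm, n_tokens) {
  if (any(n_tokens < 1)) {
    stop("uhm percentage undefined for a unit with zero tokens", call. = FALSE)
  }
  if (any(n_uhm < 0) || any(n_uhm > n_tokens)) {
    stop("need 0 <= n_uhm <= n_tokens", call. = FALSE)
  }
  100 * n_uhm / n_tokens
}

#' Duration-based filled-pause proportion
#'
#' Summed filled-pause duration over summed speech duration, as a percentage.
#' Used for role comparisons, where proportions rather than rates are
#' appropriate because speaking time differs considerably between roles.
#'
#' @param fp_duration_s Summed filled-pause duration in seconds.
#' @param speech_duration_s Summed speech duration in seconds, positive.
#' @return Percentage in `[0, 100]`.
#' @export
duration_proportion <- function(fp_duration_s, speech_duration_s) {
  if (any(!is.finite(speech_duration_s)) || any(speech_duration_s <= 0)) {
    stop("`speech_duration_s` must be positive", call. = FALSE)
  }
  100 * fp_duration_s / speech_duration_s
}

#' Per-speaker summary table
#'
#' One row per speaker in the metadata: token counts by lexical type, rate
#' per minute of dialogue (all of the dyad's dialogues pooled), uhm
#' percentage (`NA` for speakers without tokens), filled-pause and speech
#' durations and their ratio.
#'
#' @param tokens Token table from [extract_tokens()].
#' @param speech Speech inventory from [speech_inventory()].
#' @param durations Dialogue durations from [dialogue_durations()].
#' @param metadata Speaker metadata (`speaker_id`, `dyad_id`, `group`,
#'   `role`).
#' @param dialogue_map Optional tibble `dialogue_id`, `dyad_id` linking
#'   dialogues to dyads; by default every dialogue whose id contains the
#'   dyad id (or vice versa) is assigned to that dyad, which covers the
#'   one-dialogue-per-dyad layout produced by [generate_corpus()].
#' @return A tibble with columns `speaker_id`, `dyad_id`, `group`, `role`,
#'   `n_tokens`, `n_uh`, `n_uhm`, `dialogue_duration_s`, `rate_per_min`,
#'   `uhm_pct`, `fp_duration_s`, `speech_duration_s`, `fp_duration_pct`.
#' @export
speaker_summary <- function(tokens, speech, durations, metadata,
                            dialogue_map = NULL) {
  check_metadata(metadata)
  if (is.null(dialogue_map)) {
    dialogue_map <- infer_dialogue_map(durations$dialogue_id, metadata)
  }
  dyad_duration <- dialogue_map |>
    dplyr::left_join(durations, by = "dialogue_id") |>
    dplyr::group_by(.data$dyad_id) |>
    dplyr::summarise(dialogue_duration_s = sum(.data$duration_s))

  tok <- tokens |>
    dplyr::group_by(.data$speaker_id) |>
    dplyr::summarise(
      n_tokens = dplyr::n(),
      n_uh = sum(.data$lexical_type == "uh"),
      n_uhm = sum(.data$lexical_type == "uhm"),
      fp_duration_s = sum(.data$end_s - .data$start_s)
    )

  sp <- speech |>
    dplyr::group_by(.data$speaker_id) |>
    dplyr::summarise(speech_duration_s = sum(.data$total_speech_s))

  out <- metadata |>
    dplyr::select("speaker_id", "dyad_id", "group", "role") |>
    dplyr::left_join(tok, by = "speaker_id") |>
    dplyr::left_join(sp, by = "speaker_id") |>
    dplyr::left_join(dyad_duration, by = "dyad_id") |>
    dplyr::mutate(
      dplyr::across(
        c("n_tokens", "n_uh", "n_uhm", "fp_duration_s"),
        ~ tidyr::replace_na(.x, 0)
      ),
      rate_per_min = rate_per_minute(.data$n_tokens, .data$dialogue_duration_s),
      uhm_pct = ifelse(
        .data$n_tokens > 0, 100 * .data$n_uhm / .data$n_tokens, NA_real_
      ),
      fp_duration_pct = duration_proportion(
        .data$fp_duration_s, .data$speech_duration_s
      )
    )
  dplyr::select(
    out,
    "speaker_id", "dyad_id", "group", "role", "n_tokens", "n_uh", "n_uhm",
    "dialogue_duration_s", "rate_per_min", "uhm_pct",
    "fp_duration_s", "speech_duration_s", "fp_duration_pct"
  )
}

infer_dialogue_map <- function(dialogue_ids, metadata) {
  dyads <- unique(metadata$dyad_id)
  rows <- lapply(unique(dialogue_ids), function(d) {
    hit <- dyads[vapply(
      dyads,
      function(y) grepl(y, d, fixed = TRUE) || grepl(d, y, fixed = TRUE),
      TRUE
    )]
    if (length(hit) != 1L) {
      stop(
        "cannot infer the dyad of dialogue '", d,
        "'; supply `dialogue_map` explicitly",
        call. = FALSE
      )
    }
    tibble::tibble(dialogue_id = d, dyad_id = hit)
  })
  dplyr::bind_rows(rows)
}

#' Per-dyad summary table
#'
#' Rates are per speaker-minute: a speaker's rate is their token count over
#' the dialogue duration, and the dyad rate is the mean of its two speakers'
#' rates.
#'
#' @param speakers Speaker summary from [speaker_summary()].
#' @return A tibble with one row per dyad: `dyad_id`, `group`,
#'   `dialogue_duration_s`, `n_tokens`, `rate_a`, `rate_b`, `rate_per_min`
#'   (mean of the two speaker rates), `within_dyad_diff`.
#' @export
dyad_summary <- function(speakers) {
  bad <- speakers |>
    dplyr::count(.data$dyad_id) |>
    dplyr::filter(.data$n != 2L)
  if (nrow(bad) > 0L) {
    stop(
      "each dyad must have exactly two speakers; offending: ",
      paste(bad$dyad_id, collapse = ", "),
      call. = FALSE
    )
  }
  speakers |>
    dplyr::group_by(.data$dyad_id, .data$group) |>
    dplyr::summarise(
      dialogue_duration_s = .data$dialogue_duration_s[1],
      n_tokens = sum(.data$n_tokens),
      rate_a = .data$rate_per_min[1],
      rate_b = .data$rate_per_min[2],
      within_dyad_diff = within_dyad_difference(.data$rate_a, .data$rate_b),
      rate_per_min = (.data$rate_a + .data$rate_b) / 2,
      .groups = "drop"
    )
}

#' Filled-pause duration proportions by role
#'
#' Aggregates summed filled-pause duration over summed speech duration for
#' instruction givers and followers (optionally within group).
#'
#' @param speakers Speaker summary from [speaker_summary()].
#' @param by_group If `TRUE`, break down by group as well.
#' @return A tibble with (`group`,) `role`, `fp_duration_s`,
#'   `speech_duration_s`, `fp_duration_pct`.
#' @export
role_duration_proportions <- function(speakers, by_group = FALSE) {
  keys <- if (by_group) c("group", "role") else "role"
  speakers |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      fp_duration_s = sum(.data$fp_duration_s),
      speech_duration_s = sum(.data$speech_duration_s),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fp_duration_pct = duration_proportion(
        .data$fp_duration_s, .data$speech_duration_s
      )
    )
}

#' Group-level descriptives
#'
#' Headline numbers per group: pooled rate per speaker-minute (pooled tokens
#' over pooled speaker dialogue time), mean of dyad rates, mean within-dyad
#' rate difference, pooled uhm percentage, and mean token duration.
#'
#' @param speakers Speaker summary from [speaker_summary()].
#' @param dyads Dyad summary from [dyad_summary()].
#' @param tokens Token table.
#' @return A tibble with one row per group.
#' @export
group_descriptives <- function(speakers, dyads, tokens) {
  dy <- dyads |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      rate_pooled = rate_per_minute(
        sum(.data$n_tokens), 2 * sum(.data$dialogue_duration_s)
      ),
      rate_dyad_mean = mean(.data$rate_per_min),
      within_dyad_diff_mean = mean(.data$within_dyad_diff),
      within_dyad_diff_sd = stats::sd(.data$within_dyad_diff)
    )
  sp <- speakers |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_tokens = sum(.data$n_tokens),
      uhm_pct_pooled = uhm_percentage(sum(.data$n_uhm), sum(.data$n_tokens))
    )
  du <- tokens |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_duration_ms = mean(.data$duration_ms))
  dy |>
    dplyr::left_join(sp, by = "group") |>
    dplyr::left_join(du, by = "group")
}
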