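# Three-way contour classification and diversity. A token whose pitch
# movement stays within +/- 1 semitone is "level" (the canonical realisation
# of a filled pause); movement exceeding the band is a rise (positive) or a
# fall (negative). Diversity of contour use per speaker is quantified by
# Shannon entropy over the three category proportions, in bits, so the
# maximum for three categories is log2(3) ~ 1.58.

contour_levels <- function() c("rise", "level", "fall")

#' Classify a semitone difference as rise, level or fall
#'
#' The boundary is inclusive on the level side: only movements strictly
#' exceeding the threshold count as rises or falls.
#'
#' @param delta_st Numeric vector of semitone differences (positive = rise).
#' @param threshold Half-width of the level band in semitones; default 1.
#' @return A factor with levels `rise`, `level`, `fall`.
#' @examples
#' classify_contour(c(0.5, 1, -2.3, 1.7))
#' @export
classify_contour <- function(delta_st, threshold = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(delta_st))) {
    stop("`delta_st` must be finite", call. = FALSE)
  }
  out <- ifelse(abs(delta_st) <= threshold, "level",
    ifelse(delta_st > threshold, "rise", "fall")
  )
  factor(out, levels = contour_levels())
}

#' Category proportions for one unit
#'
#' Counts and proportions over the fixed category order (rise, level, fall).
#'
#' @param categories Factor or character vector of contour categories for one
#'   unit (speaker, group, or group-by-type cell); at least one value.
#' @return A named list with `counts` and `proportions`, both ordered
#'   (rise, level, fall).
#' @export
contour_proportions <- function(categories) {
  if (length(categories) == 0L) {
    stop("no measurements: proportions undefined for an empty unit",
      call. = FALSE
    )
  }
  categories <- factor(as.character(categories), levels = contour_levels())
  if (any(is.na(categories))) {
    stop("categories must be rise, level or fall", call. = FALSE)
  }
  counts <- table(categories)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, proportions = counts / sum(counts))
}

#' Shannon entropy of a proportion vector
#'
#' `H = -sum(p * log2(p))` with the convention `0 * log2(0) = 0`. In bits;
#' for three categories the maximum is `log2(3)` (about 1.58, attained at the
#' uniform distribution) and 0 means every token had the same contour.
#'
#' @param proportions Non-negative numeric vector summing to 1 (tolerance
#'   1e-9).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(1 / 3, 1 / 3, 1 / 3)) # log2(3)
#' shannon_entropy(c(0, 1, 0))             # 0
#' @export
shannon_entropy <- function(proportions) {
  if (any(!is.finite(proportions)) || any(proportions < 0)) {
    stop("proportions must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  p <- proportions[proportions > 0]
  -sum(p * log2(p))
}

#' Per-speaker contour summary with entropy
#'
#' Joins measured semitone differences to token metadata, classifies every
#' measured token, and summarises each speaker's contour-category counts,
#' proportions and Shannon entropy. Speakers without any analyzable token do
#' not appear (mirroring their exclusion from contour analyses).
#'
#' @param tokens Token table from [extract_tokens()].
#' @param measurements Measurement table from [measure_tokens()].
#' @param threshold Level-band half-width in semitones.
#' @return A tibble with one row per speaker: `speaker_id`, `dyad_id`,
#'   `group`, `n_rise`, `n_level`, `n_fall`, `n_total`, `p_rise`, `p_level`,
#'   `p_fall`, `H`.
#' @export
entropy_by_speaker <- function(tokens, measurements, threshold = 1) {
  m <- classified_tokens(tokens, measurements, threshold)
  out <- m |>
    dplyr::count(.data$speaker_id, .data$dyad_id, .data$group,
      .data$contour,
      .drop = FALSE
    ) |>
    tidyr::pivot_wider(
      names_from = "contour", values_from = "n",
      names_prefix = "n_", values_fill = 0L
    ) |>
    dplyr::filter(.data$n_rise + .data$n_level + .data$n_fall > 0L) |>
    dplyr::mutate(
      n_total = .data$n_rise + .data$n_level + .data$n_fall,
      p_rise = .data$n_rise / .data$n_total,
      p_level = .data$n_level / .data$n_total,
      p_fall = .data$n_fall / .data$n_total
    )
  out$H <- vapply(
    seq_len(nrow(out)),
    function(i) shannon_entropy(c(out$p_rise[i], out$p_level[i], out$p_fall[i])),
    0
  )
  out
}

#' Classified token table
#'
#' Inner join of tokens and their (non-excluded) measurements, with the
#' contour category attached.
#'
#' @inheritParams entropy_by_speaker
#' @return Token table restricted to measured tokens, plus `delta_st` and
#'   `contour`.
#' @export
classified_tokens <- function(tokens, measurements, threshold = 1) {
  m <- dplyr::inner_join(
    tokens,
    measurements[, c("token_id", "delta_st")],
    by = "token_id"
  )
  m$contour <- classify_contour(m$delta_st, threshold)
  m
}

#' Contour proportions by group and lexical type
#'
#' The group-by-type contingency layout: for each group and filled-pause type,
#' the percentage of tokens realised as rise, level and fall.
#'
#' @inheritParams entropy_by_speaker
#' @param by_type If `FALSE`, aggregate across lexical types.
#' @return A tibble with `group`, (`lexical_type`,) `contour`, `n`,
#'   `proportion_pct`.
#' @export
contour_table <- function(tokens, measurements, threshold = 1,
                          by_type = TRUE) {
  m <- classified_tokens(tokens, measurements, threshold)
  keys <- if (by_type) c("group", "lexical_type") else "group"
  m |>
    dplyr::count(
      dplyr::across(dplyr::all_of(keys)), .data$contour,
      .drop = FALSE
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::filter(sum(.data$n) > 0L) |>
    dplyr::mutate(proportion_pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
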