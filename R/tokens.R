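# Turn raw annotation labels into the pipeline's filled-pause token table.
#
# A filled pause is any hesitation of the form "aeh"/"aehm" (German) or
# "uh"/"uhm" (English orthography). The lexical split follows the nasal-coda
# rule: any realisation ending in a nasal -- including nasal-only "m"/"hm" --
# counts as uhm; vowel-only realisations count as uh. Everything else in a
# tier is ordinary speech.

#' Default filled-pause label table
#'
#' Maps annotation labels to the lexical types `uh` (vowel only) and `uhm`
#' (nasal coda, including nasal-only realisations). Matching is
#' case-insensitive and ignores lengthening marks (`:`, IPA length mark) and
#' surrounding whitespace; see [normalize_fp_label()]. The table covers the
#' German forms plus common English spellings and can be extended or replaced
#' by the user.
#'
#' @return A tibble with columns `label` and `lexical_type`.
#' @export
default_label_table <- function() {
  tibble::tibble(
    label = c(
      "\u00e4h", "eh", "ah", "uh", "\u00f6h", "er",
      "\u00e4hm", "ehm", "ahm", "uhm", "um", "\u00f6hm",
      "hm", "m"
    ),
    lexical_type = c(
      rep("uh", 6L),
      rep("uhm", 6L),
      rep("uhm", 2L)
    )
  )
}

#' Normalize an annotation label to a lexical type
#'
#' @param label Character vector of raw labels.
#' @param label_table Lookup table as produced by [default_label_table()].
#' @return Character vector: `"uh"`, `"uhm"`, or `NA` for labels that are not
#'   filled pauses.
#' @export
normalize_fp_label <- function(label, label_table = default_label_table()) {
  key <- tolower(trimws(label))
  key <- gsub(":|\u02d0", "", key)   # strip lengthening marks
  label_table$lexical_type[match(key, tolower(label_table$label))]
}

#' Extract filled-pause tokens from annotations
#'
#' Scans every interval tier of one or more dialogues, matches labels against
#' the normalization table, and joins speaker metadata. Tier names are taken
#' as speaker ids.
#'
#' @param annotations A `textgrid` or a list of them.
#' @param metadata A data frame with columns `speaker_id`, `dyad_id`, `group`
#'   (`ASD`/`CTR`), `role` (`giver`/`follower`).
#' @param label_table Label normalization table; see [default_label_table()].
#' @return A tibble with one row per token: `token_id`, `dialogue_id`,
#'   `speaker_id`, `dyad_id`, `group`, `role`, `lexical_type`, `start_s`,
#'   `end_s`, `duration_ms`.
#' @export
extract_tokens <- function(annotations, metadata,
                           label_table = default_label_table()) {
  annotations <- as_textgrid_list(annotations)
  check_metadata(metadata)

  speakers <- unlist(lapply(annotations, function(tg) names(tg$tiers)))
  missing <- setdiff(unique(speakers), metadata$speaker_id)
  if (length(missing) > 0L) {
    stop(
      "speaker(s) missing from metadata: ",
      paste(sort(missing), collapse = ", "),
      call. = FALSE
    )
  }

  rows <- list()
  for (tg in annotations) {
    for (sp in names(tg$tiers)) {
      tier <- tg$tiers[[sp]]
      if (nrow(tier) == 0L) next
      type <- normalize_fp_label(tier$label, label_table)
      hit <- which(!is.na(type))
      if (length(hit) == 0L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dialogue_id = tg$dialogue_id,
        speaker_id = sp,
        lexical_type = type[hit],
        start_s = tier$start_s[hit],
        end_s = tier$end_s[hit],
        token_index = seq_along(hit)
      )
    }
  }
  if (length(rows) == 0L) {
    tokens <- tibble::tibble(
      dialogue_id = character(), speaker_id = character(),
      lexical_type = character(), start_s = numeric(), end_s = numeric(),
      token_index = integer()
    )
  } else {
    tokens <- dplyr::bind_rows(rows)
  }

  tokens <- dplyr::left_join(
    tokens,
    metadata[, c("speaker_id", "dyad_id", "group", "role")],
    by = "speaker_id"
  )
  tokens <- dplyr::mutate(
    tokens,
    token_id = sprintf(
      "%s_%s_%03d", .data$dialogue_id, .data$speaker_id, .data$token_index
    ),
    duration_ms = (.data$end_s - .data$start_s) * 1000
  )
  dplyr::select(
    tokens,
    "token_id", "dialogue_id", "speaker_id", "dyad_id", "group", "role",
    "lexical_type", "start_s", "end_s", "duration_ms"
  )
}

#' Speech inventory per speaker
#'
#' Collects every non-empty labelled interval as speech (filled pauses
#' included) and sums durations per speaker. Silent stretches within an
#' interval are not subtracted.
#'
#' @param annotations A `textgrid` or a list of them.
#' @return A tibble with columns `speaker_id`, `dialogue_id`, `n_intervals`,
#'   `total_speech_s`.
#' @export
speech_inventory <- function(annotations) {
  annotations <- as_textgrid_list(annotations)
  rows <- list()
  for (tg in annotations) {
    for (sp in names(tg$tiers)) {
      tier <- tg$tiers[[sp]]
      keep <- trimws(tier$label) != ""
      rows[[length(rows) + 1L]] <- tibble::tibble(
        speaker_id = sp,
        dialogue_id = tg$dialogue_id,
        n_intervals = sum(keep),
        total_speech_s = sum(tier$end_s[keep] - tier$start_s[keep])
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Dialogue durations
#'
#' @param annotations A `textgrid` or a list of them.
#' @return A tibble with columns `dialogue_id`, `duration_s` (annotation
#'   window, task start to task end).
#' @export
dialogue_durations <- function(annotations) {
  annotations <- as_textgrid_list(annotations)
  tibble::tibble(
    dialogue_id = vapply(annotations, function(tg) tg$dialogue_id, ""),
    duration_s = vapply(annotations, function(tg) tg$xmax - tg$xmin, 0)
  )
}

as_textgrid_list <- function(annotations) {
  if (inherits(annotations, "textgrid")) {
    return(list(annotations))
  }
  if (is.list(annotations) &&
      all(vapply(annotations, inherits, TRUE, what = "textgrid"))) {
    return(annotations)
  }
  stop("`annotations` must be a textgrid or a list of textgrids",
    call. = FALSE
  )
}

check_metadata <- function(metadata) {
  need <- c("speaker_id", "dyad_id", "group", "role")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0L) {
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(metadata$group), c("ASD", "CTR"))
  if (length(bad) > 0L) {
    stop("metadata group must be ASD or CTR; found: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(metadata$role), c("giver", "follower"))
  if (length(bad) > 0L) {
    stop("metadata role must be giver or follower; found: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(metadata)
}
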