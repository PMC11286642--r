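# Readers and writers for the Praat text formats the pipeline consumes:
# TextGrid (interval annotations) and PitchTier (time-F0 pairs). Both the
# long ("verbose") and short text dialects are supported, in UTF-8 or UTF-16
# (Praat writes UTF-16 with a BOM by default). Binary variants are out of
# scope. Values appear in the same order in both dialects, so both are parsed
# through a single token stream.

read_praat_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  n <- file.size(path)
  raw <- readBin(path, "raw", n = max(n, 2L))
  enc <- "UTF-8"
  if (length(raw) >= 2) {
    if ((raw[1] == 0xfe && raw[2] == 0xff) || (raw[1] == 0xff && raw[2] == 0xfe)) {
      enc <- "UTF-16"
    }
  }
  con <- file(path, encoding = enc)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Praat quoted strings double embedded quotes; labels are assumed not to span
# physical lines (Praat does not wrap interval labels).
praat_unquote <- function(line) {
  first <- regexpr('"', line, fixed = TRUE)
  last <- max(gregexpr('"', line, fixed = TRUE)[[1]])
  s <- substr(line, first + 1L, last - 1L)
  gsub('""', '"', s, fixed = TRUE)
}

praat_quote <- function(s) {
  paste0('"', gsub('"', '""', s, fixed = TRUE), '"')
}

# Tokenize the body of a Praat text file (everything after the two header
# lines) into an ordered stream of numbers, strings and <exists> flags.
# Structural lines of the long dialect ("item []:", "intervals [3]:") carry
# no value and are skipped.
praat_tokenize <- function(lines, path) {
  toks <- vector("list", length(lines))
  k <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (grepl("^(item|intervals|points)\\s*\\[\\s*\\d*\\s*\\]\\s*:?\\s*$", ln)) next
    if (grepl('"', ln, fixed = TRUE)) {
      k <- k + 1L
      toks[[k]] <- list(type = "str", value = praat_unquote(ln), line = i)
      next
    }
    if (grepl("<exists>", ln, fixed = TRUE)) {
      k <- k + 1L
      toks[[k]] <- list(type = "exists", value = TRUE, line = i)
      next
    }
    rhs <- if (grepl("=", ln, fixed = TRUE)) {
      trimws(sub("^[^=]*=", "", ln))
    } else {
      ln
    }
    # a size annotation like "intervals: size = 3" reduces to its RHS above
    val <- suppressWarnings(as.numeric(rhs))
    if (is.na(val)) {
      stop(
        "malformed Praat text file ", path, ": cannot parse line ",
        i + 2L, ": ", lines[[i]],
        call. = FALSE
      )
    }
    k <- k + 1L
    toks[[k]] <- list(type = "num", value = val, line = i)
  }
  toks[seq_len(k)]
}

praat_stream <- function(tokens, path) {
  pos <- 0L
  list(
    take = function(type) {
      pos <<- pos + 1L
      if (pos > length(tokens)) {
        stop("malformed Praat text file ", path, ": unexpected end of file",
          call. = FALSE
        )
      }
      tok <- tokens[[pos]]
      if (!is.null(type) && tok$type != type) {
        stop(
          "malformed Praat text file ", path, ": expected ", type,
          " near line ", tok$line + 2L,
          call. = FALSE
        )
      }
      tok$value
    },
    peek_type = function() {
      if (pos >= length(tokens)) NA_character_ else tokens[[pos + 1L]]$type
    }
  )
}

check_praat_header <- function(lines, class, path) {
  if (length(lines) < 2L || !grepl("ooTextFile", lines[[1]])) {
    stop(
      "malformed Praat text file ", path,
      ": line 1 is not a 'File type = \"ooTextFile\"' header",
      call. = FALSE
    )
  }
  if (!grepl(class, lines[[2]], fixed = TRUE)) {
    stop(
      "malformed Praat text file ", path, ": line 2 does not declare class ",
      class,
      call. = FALSE
    )
  }
}

#' Read a Praat TextGrid
#'
#' Parses an interval-tier annotation file in either the long or the short
#' text dialect (UTF-8 or UTF-16). Tier names are taken as speaker ids and
#' labels are preserved verbatim. Point tiers (`TextTier`) carry no interval
#' annotation and are skipped with a message.
#'
#' @param path Path to a `.TextGrid` file.
#' @param dialogue_id Identifier for the dialogue; defaults to the file name
#'   without extension.
#' @return An object of class `textgrid`: a list with `dialogue_id`, `xmin`,
#'   `xmax` (seconds) and `tiers`, a named list of tibbles with columns
#'   `start_s`, `end_s`, `label`.
#' @seealso [write_textgrid()], [extract_tokens()]
#' @export
read_textgrid <- function(path, dialogue_id = NULL) {
  lines <- read_praat_lines(path)
  check_praat_header(lines, "TextGrid", path)
  toks <- praat_tokenize(lines[-(1:2)], path)
  st <- praat_stream(toks, path)

  xmin <- st$take("num")
  xmax <- st$take("num")
  if (st$peek_type() == "exists") st$take("exists")
  n_tiers <- as.integer(st$take("num"))

  tiers <- list()
  for (i in seq_len(n_tiers)) {
    klass <- st$take("str")
    name <- st$take("str")
    t_xmin <- st$take("num")
    t_xmax <- st$take("num")
    n_items <- as.integer(st$take("num"))
    if (identical(klass, "IntervalTier")) {
      start_s <- end_s <- numeric(n_items)
      label <- character(n_items)
      for (j in seq_len(n_items)) {
        start_s[j] <- st$take("num")
        end_s[j] <- st$take("num")
        label[j] <- st$take("str")
      }
      tier <- tibble::tibble(start_s = start_s, end_s = end_s, label = label)
      validate_intervals(tier, where = paste0(path, ", tier '", name, "'"))
      tiers[[name]] <- tier
    } else {
      # point tier: consume (time, mark) pairs, keep nothing
      for (j in seq_len(n_items)) {
        st$take("num")
        st$take("str")
      }
      message("skipping point tier '", name, "' in ", path)
    }
  }

  if (is.null(dialogue_id)) {
    dialogue_id <- sub("\\.[Tt]ext[Gg]rid$", "", basename(path))
  }
  structure(
    list(dialogue_id = dialogue_id, xmin = xmin, xmax = xmax, tiers = tiers),
    class = "textgrid"
  )
}

validate_intervals <- function(tier, where) {
  if (nrow(tier) == 0L) return(invisible(tier))
  if (any(tier$start_s < 0) || any(tier$end_s <= tier$start_s)) {
    stop("invalid interval (need 0 <= start < end) in ", where, call. = FALSE)
  }
  if (is.unsorted(tier$start_s)) {
    stop("intervals not sorted by start time in ", where, call. = FALSE)
  }
  if (nrow(tier) > 1L) {
    overlap <- tier$start_s[-1L] < tier$end_s[-nrow(tier)] - 1e-9
    if (any(overlap)) {
      stop("overlapping intervals in ", where, call. = FALSE)
    }
  }
  invisible(tier)
}

#' Write a Praat TextGrid
#'
#' Writes the long text dialect in UTF-8. Round-trips through
#' [read_textgrid()] reproduce interval times to well below 1e-6 s.
#'
#' @param tg A `textgrid` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tg, path) {
  stopifnot(inherits(tg, "textgrid"))
  num <- function(x) sprintf("%.15g", x)
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    paste0("xmin = ", num(tg$xmin)),
    paste0("xmax = ", num(tg$xmax)),
    "tiers? <exists>",
    paste0("size = ", length(tg$tiers)),
    "item []:"
  )
  for (i in seq_along(tg$tiers)) {
    tier <- tg$tiers[[i]]
    out <- c(
      out,
      sprintf("    item [%d]:", i),
      '        class = "IntervalTier"',
      paste0("        name = ", praat_quote(names(tg$tiers)[i])),
      paste0("        xmin = ", num(tg$xmin)),
      paste0("        xmax = ", num(tg$xmax)),
      paste0("        intervals: size = ", nrow(tier))
    )
    if (nrow(tier) > 0L) {
      out <- c(out, as.vector(rbind(
        sprintf("        intervals [%d]:", seq_len(nrow(tier))),
        paste0("            xmin = ", num(tier$start_s)),
        paste0("            xmax = ", num(tier$end_s)),
        paste0("            text = ", vapply(tier$label, praat_quote, ""))
      )))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a Praat PitchTier
#'
#' Parses a sampled F0 track (long or short text dialect). Unvoiced or
#' otherwise undefined stretches are represented by the absence of samples;
#' see [sample_f0()] for how gaps are treated at measurement time.
#'
#' @param path Path to a `.PitchTier` file.
#' @param speaker_id Optional speaker identifier; defaults to the file name
#'   without extension.
#' @return An object of class `pitchtier`: a list with `speaker_id`, `xmin`,
#'   `xmax` and `samples`, a tibble with columns `time_s`, `f0_hz`.
#' @export
read_pitchtier <- function(path, speaker_id = NULL) {
  lines <- read_praat_lines(path)
  check_praat_header(lines, "PitchTier", path)
  toks <- praat_tokenize(lines[-(1:2)], path)
  st <- praat_stream(toks, path)

  xmin <- st$take("num")
  xmax <- st$take("num")
  n <- as.integer(st$take("num"))
  time_s <- f0_hz <- numeric(n)
  for (j in seq_len(n)) {
    time_s[j] <- st$take("num")
    f0_hz[j] <- st$take("num")
  }
  if (n > 1L && any(diff(time_s) <= 0)) {
    stop("malformed PitchTier ", path, ": times not strictly increasing",
      call. = FALSE
    )
  }
  if (any(f0_hz <= 0)) {
    stop("malformed PitchTier ", path, ": non-positive F0 value",
      call. = FALSE
    )
  }
  if (is.null(speaker_id)) {
    speaker_id <- sub("\\.[Pp]itch[Tt]ier$", "", basename(path))
  }
  new_pitchtier(speaker_id, xmin, xmax,
    tibble::tibble(time_s = time_s, f0_hz = f0_hz)
  )
}

new_pitchtier <- function(speaker_id, xmin, xmax, samples) {
  structure(
    list(speaker_id = speaker_id, xmin = xmin, xmax = xmax, samples = samples),
    class = "pitchtier"
  )
}

#' Write a Praat PitchTier
#'
#' Writes the long text dialect in UTF-8; round-trips through
#' [read_pitchtier()] are lossless to numerical precision.
#'
#' @param pt A `pitchtier` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pitchtier <- function(pt, path) {
  stopifnot(inherits(pt, "pitchtier"))
  num <- function(x) sprintf("%.15g", x)
  s <- pt$samples
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "PitchTier"',
    "",
    paste0("xmin = ", num(pt$xmin)),
    paste0("xmax = ", num(pt$xmax)),
    paste0("points: size = ", nrow(s))
  )
  if (nrow(s) > 0L) {
    out <- c(out, as.vector(rbind(
      sprintf("points [%d]:", seq_len(nrow(s))),
      paste0("    number = ", num(s$time_s)),
      paste0("    value = ", num(s$f0_hz))
    )))
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' @export
print.textgrid <- function(x, ...) {
  cat("<textgrid> dialogue", x$dialogue_id,
    sprintf("[%.3f, %.3f] s,", x$xmin, x$xmax),
    length(x$tiers), "tier(s):",
    paste0(names(x$tiers), " (", vapply(x$tiers, nrow, 0L), ")",
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' @export
print.pitchtier <- function(x, ...) {
  cat("<pitchtier> speaker", x$speaker_id,
    sprintf("[%.3f, %.3f] s,", x$xmin, x$xmax),
    nrow(x$samples), "samples\n"
  )
  invisible(x)
}
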