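# End-to-end orchestration: extract -> measure -> classify -> summarise ->
# model, with full bookkeeping of every excluded token and a report bundle
# mirroring the analysis layout (rates, lexical choice, contour proportions
# by group and type, entropy, and the model contrasts).

#' Run the full filled-pause analysis pipeline
#'
#' @param input An `fp_corpus` (from [generate_corpus()] or [read_corpus()])
#'   or a directory path accepted by [read_corpus()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV/JSON plus a plain-text report.
#' @param threshold_st Level-band half-width in semitones for contour
#'   classification.
#' @param max_gap Voiced-run gap tolerance (s) for pitch interpolation.
#' @param smooth Median-smooth contours before measuring.
#' @param flag_implausible Screen physiologically implausible measurements;
#'   see [measure_tokens()].
#' @param models Fit the group-comparison models (set `FALSE` for a
#'   descriptives-only run).
#' @param model_method `"bootstrap"` (default: fast ML + parametric
#'   bootstrap), `"mcmc"`, or `"auto"`; see [fit_rate_model()].
#' @param n_boot,chains,iter,warmup Engine settings forwarded to the model
#'   fits.
#' @param seed Integer seed for the model draws.
#' @param verbose Print per-stage progress.
#' @return An object of class `fp_report`: a list with `config` (the echoed
#'   run settings), `tokens`, `measurements`, `exclusions`, `speakers`,
#'   `dyads`, `roles`, `contours` (group-by-type proportions), `entropy`,
#'   `descriptives`, `models` (named list of `fp_contrast`), and `counters`.
#' @export
run_pipeline <- function(input, out_dir = NULL, threshold_st = 1,
                         max_gap = 0.02, smooth = FALSE,
                         flag_implausible = FALSE, models = TRUE,
                         model_method = "bootstrap", n_boot = 500L,
                         chains = 4L, iter = 4000L, warmup = 2000L,
                         seed = 1L, verbose = TRUE) {
  if (is.character(input)) input <- read_corpus(input)
  stopifnot(inherits(input, "fp_corpus"))
  if (threshold_st <= 0) stop("`threshold_st` must be positive", call. = FALSE)
  say <- function(...) if (verbose) message(...)

  config <- list(
    threshold_st = threshold_st, max_gap = max_gap, smooth = smooth,
    flag_implausible = flag_implausible, model_method = model_method,
    n_boot = n_boot, chains = chains, iter = iter, warmup = warmup,
    seed = seed,
    synth_config = if (!is.null(input$config)) unclass(input$config)
  )

  say("stage extract: scanning ", length(input$annotations), " dialogue(s)")
  tokens <- extract_tokens(input$annotations, input$metadata)
  speech <- speech_inventory(input$annotations)
  durations <- dialogue_durations(input$annotations)
  say("stage extract: ", nrow(tokens), " filled-pause tokens")

  say("stage measure: near-edge pitch measurement")
  meas <- measure_tokens(
    tokens, input$pitch,
    max_gap = max_gap, smooth = smooth, flag_implausible = flag_implausible
  )
  n_excluded <- nrow(meas$exclusions)
  if (n_excluded > 0L) {
    tab <- table(meas$exclusions$reason)
    say(
      "stage measure: ", n_excluded, " token(s) excluded (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")"
    )
  }

  say("stage summarize")
  speakers <- speaker_summary(tokens, speech, durations, input$metadata)
  dyads <- dyad_summary(speakers)
  roles <- role_duration_proportions(speakers, by_group = TRUE)
  contours <- contour_table(tokens, meas$measurements, threshold_st)
  contours_group <- contour_table(
    tokens, meas$measurements, threshold_st,
    by_type = FALSE
  )
  entropy <- entropy_by_speaker(tokens, meas$measurements, threshold_st)
  descriptives <- group_descriptives(speakers, dyads, tokens)

  fits <- list()
  if (models) {
    say("stage compare: fitting group models (", model_method, ")")
    ct <- classified_tokens(tokens, meas$measurements, threshold_st)
    fits$rate <- fit_rate_model(
      dplyr::transmute(dyads,
        dyad_id = .data$dyad_id, group = .data$group,
        count = .data$n_tokens,
        # both partners contribute, so exposure is in speaker-minutes
        exposure_min = 2 * .data$dialogue_duration_s / 60
      ),
      method = model_method, n_boot = n_boot,
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
    sp_uhm <- dplyr::filter(speakers, .data$n_tokens > 0)
    fits$uhm <- fit_proportion_model(
      tibble::tibble(
        speaker_id = sp_uhm$speaker_id, group = sp_uhm$group,
        successes = sp_uhm$n_uhm, totals = sp_uhm$n_tokens
      ),
      method = model_method, n_boot = n_boot,
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
    fits$level <- fit_proportion_model(
      tibble::tibble(
        speaker_id = entropy$speaker_id, group = entropy$group,
        successes = entropy$n_level, totals = entropy$n_total
      ),
      method = model_method, n_boot = n_boot,
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
    by_type <- ct |>
      dplyr::group_by(.data$speaker_id, .data$group, .data$lexical_type) |>
      dplyr::summarise(
        successes = sum(.data$contour == "level"),
        totals = dplyr::n(), .groups = "drop"
      )
    fits$level_by_type <- fit_proportion_model(
      by_type,
      method = model_method, n_boot = n_boot,
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
    fits$entropy <- fit_scalar_model(
      tibble::tibble(
        unit_id = entropy$speaker_id, group = entropy$group,
        value = entropy$H
      ),
      method = model_method, n_boot = max(n_boot, 1000L),
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
    delta_sp <- ct |>
      dplyr::group_by(.data$speaker_id, .data$group) |>
      dplyr::summarise(value = mean(.data$delta_st), .groups = "drop")
    fits$delta_st <- fit_scalar_model(
      dplyr::rename(delta_sp, unit_id = "speaker_id"),
      method = model_method, n_boot = max(n_boot, 1000L),
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
  }

  report <- structure(
    list(
      config = config,
      tokens = tokens,
      measurements = meas$measurements,
      exclusions = meas$exclusions,
      speakers = speakers,
      dyads = dyads,
      roles = roles,
      contours = contours,
      contours_group = contours_group,
      entropy = entropy,
      descriptives = descriptives,
      models = fits,
      counters = list(
        n_extracted = nrow(tokens),
        n_analyzed = nrow(meas$measurements),
        n_excluded = n_excluded
      )
    ),
    class = "fp_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' CSV per table, a JSON report with descriptives, model results and the
#' echoed configuration, and a human-readable text summary.
#'
#' @param report An `fp_report`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "fp_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name),
      row.names = FALSE, fileEncoding = "UTF-8"
    )
  }
  wcsv(report$tokens, "tokens.csv")
  wcsv(report$measurements, "measurements.csv")
  wcsv(report$exclusions, "exclusions.csv")
  wcsv(report$speakers, "speakers.csv")
  wcsv(report$dyads, "dyads.csv")
  wcsv(report$roles, "role_proportions.csv")
  wcsv(report$contours, "contour_proportions.csv")
  wcsv(report$entropy, "entropy_by_speaker.csv")

  model_json <- lapply(report$models, function(m) {
    tab <- contrast_table(m)
    lapply(seq_len(nrow(tab)), function(i) {
      ct <- if (inherits(m, "fp_contrast")) m else m[[i]]
      list(
        contrast = ct$contrast,
        delta_mean = ct$delta_mean,
        ci_low = ct$ci_low,
        ci_high = ct$ci_high,
        p_delta_gt_0 = ct$p_delta_gt_0,
        n_draws = ct$n_draws,
        method = ct$method,
        diagnostics = ct$diagnostics,
        flags = ct$flags
      )
    })
  })
  jsonlite::write_json(
    list(
      config = report$config,
      counters = report$counters,
      descriptives = report$descriptives,
      models = model_json
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )

  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.fp_report <- function(x, ...) {
  cat("Filled-pause analysis report\n")
  cat("============================\n")
  cat(sprintf(
    "tokens: %d extracted, %d analyzed, %d excluded\n",
    x$counters$n_extracted, x$counters$n_analyzed, x$counters$n_excluded
  ))
  if (nrow(x$exclusions) > 0L) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  cat("\nGroup descriptives\n")
  print(as.data.frame(x$descriptives), digits = 3, row.names = FALSE)
  cat("\nRole proportions (duration-based, % of speech)\n")
  print(as.data.frame(x$roles), digits = 3, row.names = FALSE)
  cat("\nContour proportions by group (%)\n")
  print(as.data.frame(x$contours_group), digits = 3, row.names = FALSE)
  cat("\nContour proportions by group and lexical type (%)\n")
  print(as.data.frame(x$contours), digits = 3, row.names = FALSE)
  if (length(x$models) > 0L) {
    cat("\nModel contrasts\n")
    for (nm in names(x$models)) {
      m <- x$models[[nm]]
      cat("[", nm, "]\n", sep = "")
      if (inherits(m, "fp_contrast")) {
        print(m)
      } else {
        for (ct in m) print(ct)
      }
    }
  }
  invisible(x)
}
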