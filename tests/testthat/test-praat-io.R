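# Praat text-format parsing: both dialects, encodings, structure
# preservation, round trips, and error reporting.

long_tg <- c(
  'File type = "ooTextFile"',
  'Object class = "TextGrid"',
  "",
  "xmin = 0",
  "xmax = 1.5",
  "tiers? <exists>",
  "size = 1",
  "item []:",
  "    item [1]:",
  '        class = "IntervalTier"',
  '        name = "S1"',
  "        xmin = 0",
  "        xmax = 1.5",
  "        intervals: size = 3",
  "        intervals [1]:",
  "            xmin = 0",
  "            xmax = 0.2",
  '            text = ""',
  "        intervals [2]:",
  "            xmin = 0.2",
  "            xmax = 0.7",
  "            text = \"ähm\"",
  "        intervals [3]:",
  "            xmin = 0.7",
  "            xmax = 1.5",
  '            text = "genau"'
)

short_tg <- c(
  'File type = "ooTextFile"',
  'Object class = "TextGrid"',
  "",
  "0", "1.5",
  "<exists>",
  "2",
  '"IntervalTier"', '"spkA"', "0", "1.5", "1",
  "0", "0.5", "\"äh\"",
  '"IntervalTier"', '"spkB"', "0", "1.5", "2",
  "0", "1", '"ja"',
  "1", "1.5", '"sure ""thing"""'
)

write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
}

test_that("long-form TextGrid parses with verbatim labels and times", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_lines_utf8(long_tg, f)
  tg <- read_textgrid(f)
  expect_s3_class(tg, "textgrid")
  expect_equal(tg$xmax, 1.5)
  expect_named(tg$tiers, "S1")
  expect_equal(nrow(tg$tiers$S1), 3L)
  expect_equal(tg$tiers$S1$label, c("", "ähm", "genau"))
  expect_equal(tg$tiers$S1$start_s, c(0, 0.2, 0.7))
})

test_that("short-form TextGrid keeps tier file order and unescapes quotes", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_lines_utf8(short_tg, f)
  tg <- read_textgrid(f)
  expect_named(tg$tiers, c("spkA", "spkB"))
  expect_equal(tg$tiers$spkA$label, "äh")
  expect_equal(tg$tiers$spkB$label[2], 'sure "thing"')
})

test_that("UTF-16 TextGrids are read transparently", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  payload <- iconv(
    paste0(long_tg, "\n", collapse = ""), "UTF-8", "UTF-16LE",
    toRaw = TRUE
  )[[1]]
  writeBin(c(as.raw(c(0xff, 0xfe)), payload), f) # BOM + UTF-16LE body
  tg <- read_textgrid(f)
  expect_equal(tg$tiers$S1$label[2], "ähm")
})

test_that("TextGrid write/read round trip preserves intervals to 1e-6 s", {
  set.seed(5)
  bounds <- sort(runif(7, 0, 30))
  tg <- make_tg(
    start_s = bounds[-7], end_s = bounds[-1],
    label = c("", "äh", "a \"quoted\" label", "", "ähm:", "x"),
    speaker = "Spk 1", xmax = 30
  )
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(tg, f)
  tg2 <- read_textgrid(f, dialogue_id = tg$dialogue_id)
  expect_equal(tg2$tiers[["Spk 1"]]$label, tg$tiers[["Spk 1"]]$label)
  expect_lt(
    max(abs(tg2$tiers[["Spk 1"]]$start_s - tg$tiers[["Spk 1"]]$start_s)),
    1e-6
  )
  expect_lt(
    max(abs(tg2$tiers[["Spk 1"]]$end_s - tg$tiers[["Spk 1"]]$end_s)),
    1e-6
  )
})

test_that("malformed TextGrids fail with the offending line named", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_lines_utf8(c("not a praat file", "whatever"), f)
  expect_error(read_textgrid(f), "line 1")

  bad <- long_tg
  bad[16] <- "            xmin = oops"
  write_lines_utf8(bad, f)
  expect_error(read_textgrid(f), "line 16")
})

test_that("point tiers are skipped with a notice", {
  mixed <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "0", "2", "<exists>", "2",
    '"TextTier"', '"events"', "0", "2", "1",
    "0.5", '"click"',
    '"IntervalTier"', '"S1"', "0", "2", "1",
    "0", "2", '"hello"'
  )
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_lines_utf8(mixed, f)
  expect_message(tg <- read_textgrid(f), "point tier")
  expect_named(tg$tiers, "S1")
})

test_that("PitchTier parses, validates, and round trips", {
  short_pt <- c(
    'File type = "ooTextFile"',
    'Object class = "PitchTier"',
    "",
    "0", "1", "2",
    "0.1", "100",
    "0.4", "120"
  )
  f <- withr::local_tempfile(fileext = ".PitchTier")
  write_lines_utf8(short_pt, f)
  pt <- read_pitchtier(f)
  expect_equal(nrow(pt$samples), 2L)
  expect_equal(pt$samples$f0_hz, c(100, 120))

  # empty tier is valid
  write_lines_utf8(c(short_pt[1:4], "1", "0"), f)
  expect_equal(nrow(read_pitchtier(f)$samples), 0L)

  # unsorted times rejected
  write_lines_utf8(
    c(short_pt[1:6], "0.4", "100", "0.1", "120"), f
  )
  expect_error(read_pitchtier(f), "increasing")

  # non-positive F0 rejected
  write_lines_utf8(
    c(short_pt[1:6], "0.1", "100", "0.4", "-3"), f
  )
  expect_error(read_pitchtier(f), "non-positive")

  # round trip
  set.seed(9)
  orig <- make_pt(sort(runif(25, 0, 10)), runif(25, 80, 300))
  f2 <- withr::local_tempfile(fileext = ".PitchTier")
  write_pitchtier(orig, f2)
  back <- read_pitchtier(f2, speaker_id = "S1")
  expect_equal(back$samples$time_s, orig$samples$time_s, tolerance = 1e-12)
  expect_equal(back$samples$f0_hz, orig$samples$f0_hz, tolerance = 1e-12)
})
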