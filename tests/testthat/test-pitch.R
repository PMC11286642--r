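# Semitone conversion, contour interpolation, and the near-edge fallback
# rule.

test_that("hz_to_st matches the 12*log2 definition", {
  expect_equal(hz_to_st(1), 0)
  expect_equal(hz_to_st(200) - hz_to_st(100), 12)
  # 12 * log2(1.5), evaluated independently at high precision
  expect_equal(hz_to_st(150) - hz_to_st(100), 7.01955000865388, tolerance = 1e-12)
  expect_equal(hz_to_st(440, ref = 440), 0)
  expect_error(hz_to_st(0), "positive")
  expect_error(hz_to_st(-5), "positive")
  expect_error(hz_to_st(100, ref = 0), "positive")
})

test_that("semitone differences are scale-invariant and octave-additive", {
  set.seed(42)
  for (i in 1:25) {
    f1 <- runif(1, 60, 400)
    f2 <- runif(1, 60, 400)
    k <- runif(1, 0.1, 10)
    d <- hz_to_st(f2) - hz_to_st(f1)
    expect_equal(hz_to_st(k * f2) - hz_to_st(k * f1), d, tolerance = 1e-10)
    expect_equal(hz_to_st(2 * f2) - hz_to_st(f1), d + 12, tolerance = 1e-10)
  }
})

test_that("sample_f0 interpolates inside voiced runs and is NA elsewhere", {
  pt <- make_pt(c(0.0, 0.1), c(100, 120))
  expect_equal(sample_f0(pt, 0.05, max_gap = 0.2), 110)
  expect_equal(sample_f0(pt, 0.0), 100)  # exact sample hit
  expect_equal(sample_f0(pt, 0.1), 120)
  # gap wider than max_gap -> undefined between samples
  expect_true(is.na(sample_f0(pt, 0.05, max_gap = 0.05)))
  # outside the sampled range -> undefined
  expect_true(is.na(sample_f0(pt, -0.01)))
  expect_true(is.na(sample_f0(pt, 0.11)))
  # empty contour -> all undefined
  expect_true(is.na(sample_f0(make_pt(numeric(0), numeric(0)), 0.5)))
})

test_that("select_points uses 10%/90% when pitch is defined throughout", {
  pt <- make_token_contour(0, 0.5, 120, delta_st = 3)
  m <- select_points(pt, 0, 0.5, token_id = "t1")
  expect_false(m$excluded)
  expect_equal(m$start_frac, 0.1)
  expect_equal(m$end_frac, 0.9)
  # delta identity holds exactly
  expect_equal(m$delta_st, 12 * log2(m$f_end_hz / m$f_start_hz))
})

test_that("each edge falls back independently, matching the scan oracle", {
  cases <- list(
    list(drop_start = 0.15, drop_end = 0),    # expect 0.2 / 0.9
    list(drop_start = 0, drop_end = 0.15),    # expect 0.1 / 0.8
    list(drop_start = 0.35, drop_end = 0),    # expect 0.4 / 0.9
    list(drop_start = 0, drop_end = 0.25),    # expect 0.1 / 0.7
    list(drop_start = 0.22, drop_end = 0.12)  # expect 0.3 / 0.8
  )
  expected <- list(
    c(0.2, 0.9), c(0.1, 0.8), c(0.4, 0.9), c(0.1, 0.7), c(0.3, 0.8)
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    pt <- make_token_contour(
      1, 1.6, 150,
      delta_st = 2,
      drop_start = cs$drop_start, drop_end = cs$drop_end
    )
    m <- select_points(pt, 1, 1.6)
    orc <- oracle_fracs(pt, 1, 1.6)
    expect_false(m$excluded)
    expect_equal(unname(c(m$start_frac, m$end_frac)), expected[[i]])
    expect_equal(unname(c(m$start_frac, m$end_frac)), unname(orc))
  }
})

test_that("tokens with no usable window are excluded, not errored", {
  # empty contour
  m <- select_points(make_pt(numeric(0), numeric(0)), 0, 0.5)
  expect_true(m$excluded)
  expect_equal(m$reason, "empty_contour")
  # start edge voiceless beyond the 40% limit
  pt <- make_token_contour(0, 0.5, 120, drop_start = 0.45)
  m <- select_points(pt, 0, 0.5)
  expect_true(m$excluded)
  expect_equal(m$reason, "no_pitch_at_any_window")
  # end edge voiceless beyond the 30% limit
  pt <- make_token_contour(0, 0.5, 120, drop_end = 0.35)
  expect_true(select_points(pt, 0, 0.5)$excluded)
})

test_that("degenerate token spans are a validation error", {
  pt <- make_token_contour(0, 0.5, 120)
  expect_error(select_points(pt, 0.3, 0.3), "duration")
  expect_error(select_points(pt, 0.4, 0.2), "duration")
})

test_that("emitted fractions always lie on the fallback grid", {
  set.seed(99)
  for (i in 1:60) {
    pt <- make_token_contour(
      0, runif(1, 0.15, 0.8), runif(1, 80, 250),
      delta_st = runif(1, -5, 5),
      drop_start = sample(c(0, runif(1, 0, 0.5)), 1),
      drop_end = sample(c(0, runif(1, 0, 0.4)), 1)
    )
    m <- select_points(pt, pt$xmin, pt$xmax)
    if (!m$excluded) {
      expect_true(m$start_frac %in% c(0.1, 0.2, 0.3, 0.4))
      expect_true(m$end_frac %in% c(0.9, 0.8, 0.7))
      expect_lt(m$start_frac, m$end_frac)
    }
  }
})

test_that("measure_tokens yields exactly one outcome per token", {
  corp <- tiny_corpus(seed = 17)
  tok <- extract_tokens(corp$annotations, corp$metadata)
  res <- measure_tokens(tok, corp$pitch)
  expect_equal(nrow(res$measurements) + nrow(res$exclusions), nrow(tok))
  expect_length(
    intersect(res$measurements$token_id, res$exclusions$token_id), 0
  )
  expect_error(measure_tokens(tok, corp$pitch[-1]), "no pitch contour")
})

test_that("median smoothing suppresses an isolated pitch spike", {
  t <- seq(0, 0.5, by = 0.01)
  f0 <- rep(120, length(t))
  f0[25] <- 400 # single-frame octave-jump artefact
  sm <- smooth_contour(make_pt(t, f0))
  expect_equal(sm$samples$f0_hz[25], 120)
})
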