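# Group-comparison model contracts: reported quantities derive from stored
# draws, label swaps mirror the contrast, and programmed effects are
# recovered. The bootstrap engine carries most tests; the MCMC engine gets a
# contract check with short chains.

sim_rate_data <- function(n_per_group, minutes, lambda1, lambda2, seed) {
  set.seed(seed)
  tibble::tibble(
    dyad_id = sprintf("D%02d", seq_len(2 * n_per_group)),
    group = rep(c("ASD", "CTR"), each = n_per_group),
    count = stats::rpois(
      2 * n_per_group, rep(c(lambda1, lambda2), each = n_per_group) * minutes
    ),
    exposure_min = minutes
  )
}

sim_prop_data <- function(n1, n2, p1, p2, tokens, seed) {
  set.seed(seed)
  tibble::tibble(
    speaker_id = sprintf("S%02d", seq_len(n1 + n2)),
    group = rep(c("ASD", "CTR"), c(n1, n2)),
    totals = tokens,
    successes = stats::rbinom(n1 + n2, tokens, rep(c(p1, p2), c(n1, n2)))
  )
}

test_that("reported summaries are consistent with the stored draws", {
  d <- sim_rate_data(7, 20, 3.6, 3.6, seed = 101)
  fit <- fit_rate_model(d, method = "bootstrap", n_boot = 300, seed = 1)
  expect_s3_class(fit, "fp_contrast")
  expect_equal(fit$delta_mean, mean(fit$draws))
  expect_equal(fit$p_delta_gt_0, mean(fit$draws > 0))
  expect_equal(
    c(fit$ci_low, fit$ci_high),
    unname(quantile(fit$draws, c(0.025, 0.975)))
  )
  expect_lte(fit$ci_low, fit$delta_mean)
  expect_gte(fit$ci_high, fit$delta_mean)
  expect_equal(fit$n_draws, length(fit$draws))
})

test_that("relabeling the groups mirrors the rate contrast", {
  d <- sim_rate_data(7, 20, 3.0, 4.5, seed = 7)
  f1 <- fit_rate_model(d, method = "bootstrap", n_boot = 400, seed = 2)
  d2 <- d
  d2$group <- ifelse(d$group == "ASD", "CTR", "ASD")
  d2 <- d2[order(d2$group), ]
  f2 <- fit_rate_model(d2, method = "bootstrap", n_boot = 400, seed = 2)
  se <- sd(f1$draws) / sqrt(length(f1$draws))
  expect_equal(f1$delta_mean, -f2$delta_mean, tolerance = 10 * se)
  expect_equal(f1$p_delta_gt_0, 1 - f2$p_delta_gt_0, tolerance = 0.05)
})

test_that("a null rate difference yields an interval covering zero", {
  d <- sim_rate_data(7, 20, 3.6, 3.6, seed = 301)
  fit <- fit_rate_model(d, method = "bootstrap", n_boot = 400, seed = 3)
  expect_lt(fit$ci_low, 0)
  expect_gt(fit$ci_high, 0)
  expect_gt(fit$p_delta_gt_0, 0.05)
  expect_lt(fit$p_delta_gt_0, 0.95)
})

test_that("a doubled rate is detected with high posterior probability", {
  d <- sim_rate_data(14, 30, 2.0, 4.0, seed = 11)
  fit <- fit_rate_model(d, method = "bootstrap", n_boot = 400, seed = 4)
  expect_gt(fit$p_delta_gt_0, 0.95)
  expect_gt(fit$ci_low, 0)
  # log-scale contrast near log(2)
  expect_equal(fit$delta_mean, log(2), tolerance = 0.25)
})

test_that("all-zero groups are fitted but flagged", {
  d <- sim_rate_data(3, 10, 2, 2, seed = 5)
  d$count[d$group == "ASD"] <- 0L
  expect_warning(
    fit <- fit_rate_model(d, method = "bootstrap", n_boot = 150, seed = 6),
    "zero"
  )
  expect_true("all_zero_group" %in% fit$flags)
})

test_that("the proportion model recovers a programmed group difference", {
  d <- sim_prop_data(14, 13, 0.55, 0.70, tokens = 37, seed = 13)
  fit <- fit_proportion_model(d, method = "bootstrap", n_boot = 200, seed = 7)
  expect_s3_class(fit, "fp_contrast")
  # percentage-scale contrast near +15 points
  expect_equal(fit$delta_mean, 15, tolerance = 7)
  expect_gt(fit$p_delta_gt_0, 0.95)
  expect_equal(fit$p_delta_gt_0, mean(fit$draws > 0))
})

test_that("a null proportion difference is not declared", {
  d <- sim_prop_data(10, 10, 0.6, 0.6, tokens = 40, seed = 23)
  fit <- fit_proportion_model(d, method = "bootstrap", n_boot = 200, seed = 8)
  expect_lt(fit$ci_low, 0)
  expect_gt(fit$ci_high, 0)
})

test_that("the interaction model reports all requested contrasts", {
  set.seed(41)
  sp <- sprintf("S%02d", 1:20)
  d <- tibble::tibble(
    speaker_id = rep(sp, each = 2),
    group = rep(rep(c("ASD", "CTR"), each = 10), each = 2),
    lexical_type = rep(c("uh", "uhm"), 20),
    totals = 20L,
    successes = stats::rbinom(
      40, 20,
      ifelse(rep(rep(c(TRUE, FALSE), each = 10), each = 2), 0.55, 0.70)
    )
  )
  fits <- fit_proportion_model(d, method = "bootstrap", n_boot = 150, seed = 9)
  expect_type(fits, "list")
  expect_length(fits, 5L)
  nms <- names(fits)
  expect_true(any(grepl("interaction", nms)))
  expect_true(any(grepl("CTR - ASD \\| uh$", nms)))
  expect_true(any(grepl("uhm - uh \\| ASD", nms)))
  for (f in fits) {
    expect_s3_class(f, "fp_contrast")
    expect_equal(f$p_delta_gt_0, mean(f$draws > 0))
  }
})

test_that("a single-speaker group runs but is flagged", {
  d <- sim_prop_data(1, 6, 0.5, 0.6, tokens = 30, seed = 31)
  expect_warning(
    fit <- fit_proportion_model(d, method = "bootstrap", n_boot = 120, seed = 10),
    "single speaker"
  )
  expect_true("unidentifiable_random_effect" %in% fit$flags)
})

test_that("the scalar model is translation-invariant and recovers a shift", {
  set.seed(19)
  d <- tibble::tibble(
    unit_id = sprintf("S%02d", 1:28),
    group = rep(c("ASD", "CTR"), each = 14),
    value = stats::rnorm(28, rep(c(1.4, 1.12), each = 14), 0.25)
  )
  f1 <- fit_scalar_model(d, method = "bootstrap", n_boot = 600, seed = 12)
  d2 <- d
  d2$value <- d$value + 10
  f2 <- fit_scalar_model(d2, method = "bootstrap", n_boot = 600, seed = 12)
  expect_equal(f1$draws, f2$draws, tolerance = 1e-9)
  # the ML centre of the draws is the realized difference of sample means
  sample_diff <- mean(d$value[d$group == "CTR"]) -
    mean(d$value[d$group == "ASD"])
  expect_equal(f1$delta_mean, sample_diff, tolerance = 0.05)
  expect_lt(f1$delta_mean, 0)

  expect_error(
    fit_scalar_model(
      tibble::tibble(
        unit_id = 1:4, group = c("A", "A", "B", "B"), value = c(1, 1, 2, 2)
      ),
      method = "bootstrap"
    ),
    "zero variance"
  )
})

test_that("the MCMC engine honours the same contract", {
  d <- sim_rate_data(7, 20, 2.5, 5.0, seed = 61)
  fit <- fit_rate_model(
    d, method = "mcmc", chains = 2, iter = 1200, warmup = 400, seed = 21
  )
  expect_equal(fit$method, "mcmc")
  expect_equal(fit$n_draws, 2 * 800)
  expect_equal(fit$p_delta_gt_0, mean(fit$draws > 0))
  expect_gt(fit$p_delta_gt_0, 0.9)
  expect_lt(fit$diagnostics$rhat_max, 1.1)

  dp <- sim_prop_data(8, 8, 0.4, 0.75, tokens = 40, seed = 71)
  fp <- fit_proportion_model(
    dp, method = "mcmc", chains = 2, iter = 1000, warmup = 400, seed = 22
  )
  expect_gt(fp$p_delta_gt_0, 0.9)
  expect_equal(fp$delta_mean, 35, tolerance = 12)

  ds <- tibble::tibble(
    unit_id = 1:20, group = rep(c("A", "B"), each = 10),
    value = c(stats::rnorm(10, 0, 1), stats::rnorm(10, 1.5, 1))
  )
  fs <- fit_scalar_model(
    ds, method = "mcmc", chains = 2, iter = 1000, warmup = 400, seed = 23
  )
  expect_equal(fs$p_delta_gt_0, mean(fs$draws > 0))
})
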