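# Group-comparison models. Three structures cover every contrast in the
# analysis: a negative-binomial count model with a log-exposure offset for
# rates by dyad, a hierarchical binomial (logit) model with a per-speaker
# random intercept for proportions (uhm choice, level-contour use, with an
# optional group-by-type interaction), and a Gaussian model for per-unit
# scalars (entropy, mean semitone difference).
#
# Every fit reports the same contract: posterior mean of the difference
# delta, its 95% credible interval, and P(delta > 0), computed from stored
# draws. Two engines produce the draws: MCMC through JAGS with regularising
# weakly informative priors (normal(0, 2.5) coefficients, half-normal scales,
# exponential NB shape; 4 chains x 4000 iterations, 2000 warm-up by
# default), and a fast maximum-likelihood + parametric-bootstrap alternative
# whose draw distribution plays the same role. No significance labels are
# attached; the interval and P(delta > 0) are the result.

new_fp_contrast <- function(contrast, draws, method,
                            diagnostics = list(
                              rhat_max = NA_real_, divergences = 0L
                            ),
                            flags = character()) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 10L) {
    stop("too few usable draws for contrast '", contrast, "'", call. = FALSE)
  }
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  structure(
    list(
      contrast = contrast,
      delta_mean = mean(draws),
      ci_low = ci[1],
      ci_high = ci[2],
      p_delta_gt_0 = mean(draws > 0),
      n_draws = length(draws),
      method = method,
      diagnostics = diagnostics,
      flags = flags,
      draws = draws
    ),
    class = "fp_contrast"
  )
}

#' @export
print.fp_contrast <- function(x, ...) {
  cat(sprintf(
    "%s: mean delta = %.3f, 95%% CI [%.3f, %.3f], P(delta>0) = %.3f (%s, %d draws)\n",
    x$contrast, x$delta_mean, x$ci_low, x$ci_high, x$p_delta_gt_0,
    x$method, x$n_draws
  ))
  if (length(x$flags) > 0L) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate one or more group-comparison results
#'
#' @param x An `fp_contrast` or a list of them.
#' @return A tibble with one row per contrast.
#' @export
contrast_table <- function(x) {
  if (inherits(x, "fp_contrast")) x <- list(x)
  dplyr::bind_rows(lapply(x, function(ct) {
    tibble::tibble(
      contrast = ct$contrast,
      delta_mean = ct$delta_mean,
      ci_low = ct$ci_low,
      ci_high = ct$ci_high,
      p_delta_gt_0 = ct$p_delta_gt_0,
      n_draws = ct$n_draws,
      method = ct$method,
      flags = paste(ct$flags, collapse = ";")
    )
  }))
}

resolve_method <- function(method) {
  method <- match.arg(method, c("auto", "mcmc", "bootstrap"))
  if (method == "auto") {
    method <- if (requireNamespace("rjags", quietly = TRUE)) "mcmc" else "bootstrap"
  }
  if (method == "mcmc" && !requireNamespace("rjags", quietly = TRUE)) {
    stop("method 'mcmc' needs the rjags package; use method = 'bootstrap'",
      call. = FALSE
    )
  }
  method
}

as_group_factor <- function(group) {
  g <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(g) != 2L) {
    stop("`group` must have exactly two levels", call. = FALSE)
  }
  g
}

run_jags <- function(model_string, data, params, chains, iter, warmup, seed) {
  inits <- lapply(seq_len(chains), function(i) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (if (is.null(seed)) 1L else as.integer(seed)) + i
    )
  })
  m <- rjags::jags.model(
    textConnection(model_string),
    data = data, inits = inits, n.chains = chains, quiet = TRUE
  )
  stats::update(m, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(
    m, params, n.iter = iter - warmup, progress.bar = "none"
  )
  rhat <- NA_real_
  if (chains > 1L && requireNamespace("coda", quietly = TRUE)) {
    rhat <- tryCatch(
      max(coda::gelman.diag(samp, multivariate = FALSE)$psrf[, 1]),
      error = function(e) NA_real_
    )
  }
  draws <- do.call(rbind, lapply(samp, as.matrix))
  list(draws = draws, rhat = rhat)
}

#' Fit the rate model: negative binomial with exposure offset
#'
#' Models dyad-level token counts with a log link and a log-exposure offset,
#' so the group coefficient is a log rate ratio. The reported contrast is
#' second group level minus first on the log-rate scale.
#'
#' @param data A data frame with columns `dyad_id`, `group` (two levels),
#'   `count` (non-negative integer) and `exposure_min` (dialogue minutes,
#'   positive).
#' @param method `"auto"` (MCMC when rjags is installed, else bootstrap),
#'   `"mcmc"`, or `"bootstrap"` (maximum likelihood plus parametric
#'   bootstrap).
#' @param chains,iter,warmup MCMC settings; defaults 4 chains of 4000
#'   iterations with 2000 warm-up.
#' @param n_boot Bootstrap replicates for `method = "bootstrap"`.
#' @param prior_sd Prior SD of the normal priors on intercept and group
#'   coefficient (MCMC only).
#' @param seed Optional integer seed for the draws.
#' @return An `fp_contrast`.
#' @export
fit_rate_model <- function(data, method = "auto", chains = 4L, iter = 4000L,
                           warmup = 2000L, n_boot = 1000L, prior_sd = 2.5,
                           seed = NULL) {
  method <- resolve_method(method)
  stopifnot(all(c("group", "count", "exposure_min") %in% names(data)))
  g <- as_group_factor(data$group)
  if (any(table(g) < 2L)) {
    stop("need at least 2 dyads per group", call. = FALSE)
  }
  if (any(data$count < 0) || any(data$exposure_min <= 0)) {
    stop("counts must be >= 0 and exposures > 0", call. = FALSE)
  }
  flags <- character()
  zero <- tapply(data$count, g, function(x) all(x == 0))
  if (any(zero)) {
    warning("all counts are zero in group ", names(zero)[zero][1])
    flags <- c(flags, "all_zero_group")
  }
  contrast <- paste0(
    "log rate: ", levels(g)[2], " - ", levels(g)[1]
  )
  g01 <- as.integer(g) - 1L
  if (!is.null(seed)) set.seed(seed)

  if (method == "bootstrap") {
    df <- data.frame(y = data$count, g01 = g01, le = log(data$exposure_min))
    fit <- suppressWarnings(
      MASS::glm.nb(y ~ g01 + offset(le), data = df)
    )
    mu <- stats::fitted(fit)
    theta <- fit$theta
    draws <- vapply(seq_len(n_boot), function(b) {
      df$y <- stats::rnbinom(nrow(df), mu = mu, size = theta)
      tryCatch(
        suppressWarnings(
          stats::coef(MASS::glm.nb(y ~ g01 + offset(le), data = df))[["g01"]]
        ),
        error = function(e) {
          stats::coef(stats::glm(y ~ g01 + offset(le),
            family = stats::poisson(), data = df
          ))[["g01"]]
        }
      )
    }, 0)
    return(new_fp_contrast(contrast, draws, "bootstrap", flags = flags))
  }

  model <- "
  model {
    for (i in 1:N) {
      y[i] ~ dnegbin(pp[i], r)
      pp[i] <- r / (r + mu[i])
      log(mu[i]) <- b0 + bg * g[i] + le[i]
    }
    b0 ~ dnorm(0, tau_b)
    bg ~ dnorm(0, tau_b)
    r ~ dexp(0.1)
  }"
  res <- run_jags(
    model,
    data = list(
      y = as.integer(data$count), g = g01, le = log(data$exposure_min),
      N = nrow(data), tau_b = 1 / prior_sd^2
    ),
    params = "bg", chains = chains, iter = iter, warmup = warmup, seed = seed
  )
  new_fp_contrast(
    contrast, res$draws[, "bg"], "mcmc",
    diagnostics = list(rhat_max = res$rhat, divergences = 0L),
    flags = flags
  )
}

proportion_contrasts <- function(b0, bg, bt = NULL, bgt = NULL,
                                 glev, tlev = NULL) {
  if (is.null(bt)) {
    out <- list(100 * (stats::plogis(b0 + bg) - stats::plogis(b0)))
    names(out) <- paste0("pct: ", glev[2], " - ", glev[1])
    return(out)
  }
  p00 <- stats::plogis(b0)
  p10 <- stats::plogis(b0 + bg)
  p01 <- stats::plogis(b0 + bt)
  p11 <- stats::plogis(b0 + bg + bt + bgt)
  out <- list(
    100 * (p10 - p00),
    100 * (p11 - p01),
    100 * (p01 - p00),
    100 * (p11 - p10),
    100 * ((p11 - p01) - (p10 - p00))
  )
  names(out) <- c(
    paste0("pct: ", glev[2], " - ", glev[1], " | ", tlev[1]),
    paste0("pct: ", glev[2], " - ", glev[1], " | ", tlev[2]),
    paste0("pct: ", tlev[2], " - ", tlev[1], " | ", glev[1]),
    paste0("pct: ", tlev[2], " - ", tlev[1], " | ", glev[2]),
    "pct: interaction (group difference in type effect)"
  )
  out
}

#' Fit the proportion model: hierarchical binomial with speaker intercepts
#'
#' Binomial likelihood on per-speaker successes/totals with a logit link, a
#' per-speaker random intercept, a group fixed effect and (optionally) a
#' lexical-type fixed effect plus group-by-type interaction. Contrasts are
#' reported on the percentage scale, as differences of population-level
#' probabilities (random intercept at zero): the group difference (within
#' each type), the type difference (within each group), and the interaction.
#'
#' @param data A data frame with columns `speaker_id`, `group`, `successes`,
#'   `totals` (at least 1), and optionally `lexical_type` for the interaction
#'   model (one row per speaker, or per speaker and type).
#' @inheritParams fit_rate_model
#' @return An `fp_contrast` (group-only model) or a named list of
#'   `fp_contrast` objects (interaction model).
#' @export
fit_proportion_model <- function(data, method = "auto", chains = 4L,
                                 iter = 4000L, warmup = 2000L,
                                 n_boot = 500L, prior_sd = 2.5,
                                 seed = NULL) {
  method <- resolve_method(method)
  stopifnot(all(c("speaker_id", "group", "successes", "totals") %in% names(data)))
  if (any(data$totals < 1)) {
    stop("every unit needs totals >= 1", call. = FALSE)
  }
  if (any(data$successes < 0) || any(data$successes > data$totals)) {
    stop("need 0 <= successes <= totals", call. = FALSE)
  }
  g <- as_group_factor(data$group)
  has_type <- "lexical_type" %in% names(data)
  tf <- if (has_type) factor(data$lexical_type) else NULL
  if (has_type && nlevels(tf) != 2L) {
    stop("`lexical_type` must have exactly two levels", call. = FALSE)
  }

  flags <- character()
  n_speakers <- tapply(data$speaker_id, g, function(x) length(unique(x)))
  if (any(n_speakers < 2L)) {
    flags <- c(flags, "unidentifiable_random_effect")
    warning("a group has a single speaker; the random effect is not identifiable")
  }
  prop <- tapply(data$successes, g, sum) / tapply(data$totals, g, sum)
  if (any(prop %in% c(0, 1))) {
    flags <- c(flags, "boundary_proportions")
    warning("a group is entirely at 0% or 100%; estimates rely on regularisation")
  }

  df <- data.frame(
    s = data$successes,
    f = data$totals - data$successes,
    g01 = as.integer(g) - 1L,
    speaker_id = as.factor(data$speaker_id)
  )
  if (has_type) df$t01 <- as.integer(tf) - 1L
  if (!is.null(seed)) set.seed(seed)

  if (method == "bootstrap") {
    form <- if (has_type) {
      cbind(s, f) ~ g01 * t01 + (1 | speaker_id)
    } else {
      cbind(s, f) ~ g01 + (1 | speaker_id)
    }
    ctrl <- lme4::glmerControl(
      calc.derivs = FALSE,
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
    )
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(form, data = df, family = stats::binomial(), control = ctrl)
    ))
    extract <- function(m) {
      fe <- lme4::fixef(m)
      if (has_type) {
        c(fe[["(Intercept)"]], fe[["g01"]], fe[["t01"]], fe[["g01:t01"]])
      } else {
        c(fe[["(Intercept)"]], fe[["g01"]])
      }
    }
    boo <- suppressWarnings(suppressMessages(
      lme4::bootMer(fit, extract, nsim = n_boot, type = "parametric")
    ))
    mat <- boo$t[stats::complete.cases(boo$t), , drop = FALSE]
    cs <- if (has_type) {
      proportion_contrasts(mat[, 1], mat[, 2], mat[, 3], mat[, 4],
        glev = levels(g), tlev = levels(tf)
      )
    } else {
      proportion_contrasts(mat[, 1], mat[, 2], glev = levels(g))
    }
    out <- mapply(
      function(d, nm) new_fp_contrast(nm, d, "bootstrap", flags = flags),
      cs, names(cs),
      SIMPLIFY = FALSE
    )
    return(if (length(out) == 1L) out[[1]] else out)
  }

  sp <- as.integer(df$speaker_id)
  base <- "
  model {
    for (i in 1:N) {
      s[i] ~ dbin(pp[i], n[i])
      logit(pp[i]) <- %s + u[sp[i]]
    }
    for (j in 1:S) { u[j] ~ dnorm(0, tau_u) }
    tau_u <- pow(sigma_u, -2)
    sigma_u ~ dnorm(0, tau_b) T(0,)
    b0 ~ dnorm(0, tau_b)
    bg ~ dnorm(0, tau_b)
    %s
  }"
  model <- if (has_type) {
    sprintf(
      base,
      "b0 + bg * g[i] + bt * t[i] + bgt * g[i] * t[i]",
      "bt ~ dnorm(0, tau_b)\n    bgt ~ dnorm(0, tau_b)"
    )
  } else {
    sprintf(base, "b0 + bg * g[i]", "")
  }
  jd <- list(
    s = as.integer(df$s), n = as.integer(data$totals), g = df$g01,
    sp = sp, N = nrow(df), S = max(sp), tau_b = 1 / prior_sd^2
  )
  if (has_type) jd$t <- df$t01
  params <- if (has_type) c("b0", "bg", "bt", "bgt") else c("b0", "bg")
  res <- run_jags(model, jd, params, chains, iter, warmup, seed)
  diag <- list(rhat_max = res$rhat, divergences = 0L)
  mat <- res$draws
  cs <- if (has_type) {
    proportion_contrasts(mat[, "b0"], mat[, "bg"], mat[, "bt"], mat[, "bgt"],
      glev = levels(g), tlev = levels(tf)
    )
  } else {
    proportion_contrasts(mat[, "b0"], mat[, "bg"], glev = levels(g))
  }
  out <- mapply(
    function(d, nm) {
      new_fp_contrast(nm, d, "mcmc", diagnostics = diag, flags = flags)
    },
    cs, names(cs),
    SIMPLIFY = FALSE
  )
  if (length(out) == 1L) out[[1]] else out
}

#' Fit the scalar model: Gaussian group comparison
#'
#' Linear model of a per-unit scalar (entropy, mean semitone difference) on
#' group, with weakly informative priors in the MCMC engine (coefficients
#' normal with SD `prior_sd` on the standardized scale, half-normal residual
#' SD). The contrast is reported on the raw scale of the response.
#'
#' @param data A data frame with columns `unit_id`, `group`, `value`.
#' @inheritParams fit_rate_model
#' @return An `fp_contrast`.
#' @export
fit_scalar_model <- function(data, method = "auto", chains = 4L,
                             iter = 4000L, warmup = 2000L, n_boot = 2000L,
                             prior_sd = 2.5, seed = NULL) {
  method <- resolve_method(method)
  stopifnot(all(c("group", "value") %in% names(data)))
  g <- as_group_factor(data$group)
  if (any(table(g) < 2L)) {
    stop("need at least 2 units per group", call. = FALSE)
  }
  if (all(tapply(data$value, g, stats::var) == 0)) {
    stop("zero variance in both groups: nothing to estimate", call. = FALSE)
  }
  contrast <- paste0(levels(g)[2], " - ", levels(g)[1])
  g01 <- as.integer(g) - 1L
  if (!is.null(seed)) set.seed(seed)

  if (method == "bootstrap") {
    fit <- stats::lm(data$value ~ g01)
    mu <- stats::fitted(fit)
    sig <- stats::sigma(fit)
    draws <- vapply(seq_len(n_boot), function(b) {
      ystar <- mu + stats::rnorm(length(mu), 0, sig)
      stats::coef(stats::lm(ystar ~ g01))[["g01"]]
    }, 0)
    return(new_fp_contrast(contrast, draws, "bootstrap"))
  }

  mu_y <- mean(data$value)
  sd_y <- stats::sd(data$value)
  if (sd_y == 0) sd_y <- 1
  model <- "
  model {
    for (i in 1:N) {
      y[i] ~ dnorm(b0 + bg * g[i], tau)
    }
    b0 ~ dnorm(0, tau_b)
    bg ~ dnorm(0, tau_b)
    tau <- pow(sigma, -2)
    sigma ~ dnorm(0, tau_b) T(0,)
  }"
  res <- run_jags(
    model,
    data = list(
      y = (data$value - mu_y) / sd_y, g = g01, N = nrow(data),
      tau_b = 1 / prior_sd^2
    ),
    params = "bg", chains = chains, iter = iter, warmup = warmup, seed = seed
  )
  new_fp_contrast(
    contrast, res$draws[, "bg"] * sd_y, "mcmc",
    diagnostics = list(rhat_max = res$rhat, divergences = 0L)
  )
}
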