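test_that("censored lognormal MLE recovers parameters and matches a hand-written likelihood", {
  set.seed(201)
  x <- rlnorm(5000, 1.96, 0.27)
  fit <- fit_censored(x, FALSE, "lognormal")
  expect_equal(unname(fit$estimate["meanlog"]), 1.96, tolerance = 0.02)
  expect_equal(unname(fit$estimate["sdlog"]), 0.27, tolerance = 0.02)
  # uncensored fit equals the closed-form MLE of the log sample
  expect_equal(unname(fit$estimate["meanlog"]), mean(log(x)), tolerance = 1e-4)

  # right-censor at 12 h (~14% of the mass) and compare against the
  # independent optim route on the explicit censored log-likelihood
  cens <- x > 12
  xc <- ifelse(cens, 12, x)
  fitc <- fit_censored(xc, cens, "lognormal")
  oracle <- censored_lnorm_mle(xc, cens)
  expect_equal(unname(fitc$estimate["meanlog"]), unname(oracle["meanlog"]),
               tolerance = 2e-3)
  expect_equal(unname(fitc$estimate["meanlog"]), 1.96, tolerance = 0.03)
  expect_equal(fitc$loglik, -unname(oracle["nll"]), tolerance = 0.01)

  expect_error(fit_censored(rep(5, 10), FALSE, "lognormal"), "degenerate")
})

test_that("BIC ranking prefers the generating family and applies the penalty formula", {
  # formula: k ln n - 2 loglik
  set.seed(202)
  x <- rlnorm(400, 1.96, 0.27)
  rk <- bic_rank(x)
  expect_identical(rk$family[1], "lognormal")
  expect_gt(rk$delta_bic[rk$family == "normal"], 2)
  expect_equal(rk$bic, rk$n_params * log(400) - 2 * rk$loglik)
  # equal fit, fewer parameters wins: check the formula directly
  expect_equal(2 * log(100) + 500, 509.2103, tolerance = 1e-4)
  # gamma parameter-count override flows into the penalty
  rk4 <- bic_rank(x, gamma_n_params = 4)
  expect_equal(rk4$bic[rk4$family == "gamma"] -
                 rk$bic[rk$family == "gamma"], 2 * log(400))
})

test_that("BIC ranking is invariant to duration rescaling for scale families", {
  set.seed(203)
  x <- rlnorm(400, 1.96, 0.27)
  rk_h <- bic_rank(x, families = c("lognormal", "weibull"))
  rk_m <- bic_rank(x * 60, families = c("lognormal", "weibull"))
  expect_identical(rk_h$family, rk_m$family)
  expect_equal(rk_h$delta_bic, rk_m$delta_bic, tolerance = 0.02)
})

test_that("Pearson correlation matches the bivariate-lognormal closed form", {
  set.seed(204)
  expect_equal(pearson_ci(1:10, 1:10 * 2)$estimate, 1)
  pp <- phase_params(1.96, 0.27, 2.18, 0.19,
                     rho_log = rho_log_for_duration_corr(0.33, 0.27, 0.19))
  d <- sample_phase_durations(1e5, pp)
  obs <- pearson_ci(d$t_g1, d$t_g1 + d$t_s)
  # closed form: rho = (v1 + c) / (s1 sqrt(v1 + v2 + 2c)) from lognormal
  # moments of the two phases
  m1 <- exp(1.96 + 0.27^2 / 2); m2 <- exp(2.18 + 0.19^2 / 2)
  v1 <- m1^2 * expm1(0.27^2); v2 <- m2^2 * expm1(0.19^2)
  cc <- 0.33 * sqrt(v1 * v2)
  rho_expect <- (v1 + cc) / (sqrt(v1) * sqrt(v1 + v2 + 2 * cc))
  expect_equal(obs$estimate, rho_expect, tolerance = 0.01)
  # independent samples: CI covers 0
  ind <- pearson_ci(rnorm(500), rnorm(500))
  expect_true(ind$conf.low < 0 && ind$conf.high > 0)
})

test_that("rank-sum test is calibrated and detects separation", {
  set.seed(205)
  a <- rlnorm(100, 1, 0.3)
  expect_gte(rank_sum_test(a, a)$p.value, 0.99)
  expect_lt(rank_sum_test(a + 10 * sd(a), a)$p.value, 1e-10)
  # type-I error at alpha = 0.05 under the null
  rej <- mean(replicate(1000, {
    rank_sum_test(rlnorm(400, 1.96, 0.27), rlnorm(400, 1.96, 0.27))$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("both proportion-comparison criteria are computed and labeled", {
  eq <- proportion_difference(30, 100, 60, 200)
  expect_false(eq$z_test_significant)
  expect_false(eq$margin_significant)
  # the study's death probabilities at its approximate group sizes
  res <- proportion_difference(418, 550, 360, 500)
  expect_true(res$margin_significant)
  # oracle formula for the pooled z-test
  pb <- (418 + 360) / (550 + 500)
  z <- (418 / 550 - 360 / 500) / sqrt(pb * (1 - pb) * (1 / 550 + 1 / 500))
  expect_equal(res$z_test_p, 2 * pnorm(-abs(z)))
  # the two criteria genuinely disagree on this input
  expect_false(res$z_test_significant)
  ext <- proportion_difference(100, 100, 0, 100)
  expect_true(ext$z_test_significant && ext$margin_significant)
})

test_that("track tables feed the censored per-phase fits", {
  cfg <- experiment_config(n_cells = 2000)
  tracks <- simulate_tracks(cfg, seed = 206)
  fp <- fit_phases(tracks)
  expect_identical(nrow(fp), 8L)
  expect_setequal(unique(fp$phase_at_trail), c("G1", "SG2M"))
  best <- fp[fp$delta_bic == 0, ]
  expect_true(all(best$converged))
})
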