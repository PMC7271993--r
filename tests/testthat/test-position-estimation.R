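test_that("the dying-cell position estimator matches a quadrature oracle", {
  pp <- nci_params()
  set.seed(501)
  expect_equal(estimate_c0_dying(0, "G1", pp, 200), 0, tolerance = 1e-12)
  expect_equal(estimate_c0_dying(0, "SG2M", pp, 200), 0.45, tolerance = 1e-12)
  # d far in the tail: E[d/p | p > d] -> 1, so the estimate approaches the
  # phase end
  expect_gt(estimate_c0_dying(25, "G1", pp, 2000), 0.42)
  # quadrature oracle for E[d/p | p > d] at d = 7.4
  d <- 7.4
  num <- integrate(function(p) (d / p) * dlnorm(p, 1.96, 0.27), d, Inf)$value
  den <- plnorm(d, 1.96, 0.27, lower.tail = FALSE)
  oracle <- 0.45 * num / den
  est <- replicate(20, estimate_c0_dying(d, "G1", pp, 4000))
  expect_lt(abs(mean(est) - oracle), 3 * sd(est) / sqrt(20) + 1e-3)
  # truncation beyond numerical support errors
  expect_error(estimate_c0_dying(1e6, "G1", pp, 100), "support")
})

test_that("Monte-Carlo error of the resampled estimator scales as 1/sqrt(m)", {
  pp <- nci_params()
  set.seed(502)
  s_small <- sd(replicate(40, estimate_c0_dying(6, "G1", pp, 100)))
  s_big <- sd(replicate(40, estimate_c0_dying(6, "G1", pp, 10000)))
  expect_gt(s_small / s_big, 5)
  expect_lt(s_small / s_big, 20)
})

test_that("the survivor-branch estimator inverts the prolongation exactly", {
  pp <- nci_params()
  expect_equal(estimate_c0_survivor(9.2, 3.7, 3.6, "G1", pp),
               0.45 * 3.7 / 7.4, tolerance = 1e-12)
  expect_equal(estimate_c0_survivor(10, 2, 0, "G1", pp), 0.45 * 2 / 10)
  # zero bias on noiseless virtual data with deaths disabled
  set.seed(503)
  cfg <- experiment_config(n_cells = 1000, z_true = 3.6, death_prob_g1 = 0,
                           death_prob_s = 0, snap_to_grid = FALSE)
  tr <- simulate_tracks(cfg, seed = 503)
  est <- estimate_positions(tr, 3.6, "hybrid_I", pp)
  ok <- !is.na(est$c0_hat)
  expect_gt(sum(ok), 500)
  expect_lt(max(abs(est$c0_hat[ok] - est$c0_true[ok])), 1e-6)
})

test_that("all estimates stay inside the treated phase's interval", {
  pp <- nci_params()
  set.seed(504)
  cfg <- experiment_config(n_cells = 3000, z_true = 3.6)
  tr <- simulate_tracks(cfg, seed = 504)
  for (st in c("hybrid_I", "truncated_II", "untruncated_III")) {
    est <- estimate_positions(tr, 3.6, st, pp, m_resamples = 200)
    g1 <- est$c0_hat[est$phase_at_trail == "G1"]
    sg <- est$c0_hat[est$phase_at_trail == "SG2M"]
    expect_true(all(g1 >= 0 & g1 < 0.45, na.rm = TRUE))
    expect_true(all(sg >= 0.45 & sg < 1, na.rm = TRUE))
  }
})

test_that("hybrid and truncated strategies coincide on an all-dying table", {
  pp <- nci_params()
  cfg <- experiment_config(n_cells = 500, death_prob_g1 = 1, death_prob_s = 1,
                           death_model = death_lognormal(0.3, 0.3))
  tr <- simulate_tracks(cfg, seed = 505)
  dying <- tr[tr$phase_end_censored & !is.na(tr$death_h), ]
  expect_gt(nrow(dying), 200)
  set.seed(506)
  a <- estimate_positions(dying, 3.6, "hybrid_I", pp, m_resamples = 300)
  set.seed(506)
  b <- estimate_positions(dying, 3.6, "truncated_II", pp, m_resamples = 300)
  expect_equal(a$c0_hat, b$c0_hat)
})

test_that("fate association test is calibrated and detects position-linked survival", {
  set.seed(507)
  # null: fates independent of position
  rej <- mean(replicate(1000, {
    n <- 60
    fake <- tibble::tibble(
      phase_at_trail = "SG2M",
      c0_hat = runif(n, 0.45, 1),
      fate = sample(c("apoptotic", "survivor"), n, replace = TRUE))
    fate_vs_position_test(fake)$p.value[2] < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # directional: cells exposed earlier in S/G2/M survive more often
  set.seed(508)
  c0 <- runif(800, 0.45, 1)
  p_surv <- 0.85 - 0.8 * (c0 - 0.45) / 0.55
  fate <- ifelse(runif(800) < p_surv, "survivor", "apoptotic")
  fake <- tibble::tibble(phase_at_trail = "SG2M", c0_hat = c0, fate = fate)
  res <- fate_vs_position_test(fake)
  res <- res[res$phase_at_trail == "SG2M", ]
  expect_lt(res$median_survivor, res$median_apoptotic)
  expect_lt(res$p.value, 0.05)
})
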