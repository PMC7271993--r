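test_that("virtual cohorts reproduce the control distribution when z = 0 and nothing dies", {
  pp <- nci_params()
  set.seed(401)
  coh <- build_virtual_cohort(0, "G1", pp, death_sample = list(mu_d = 1,
                                                               sigma_d = 0.39),
                              surviving_fraction = 1, n = 5e4)
  expect_equal(mean(coh$p), exp(1.96 + 0.27^2 / 2), tolerance = 0.03)
  expect_true(all(coh$survivor))
  # the forward map is exact at d = 0: p = T + z
  coh2 <- build_virtual_cohort(3.6, "G1", pp, list(mu_d = 1, sigma_d = 0.39),
                               surviving_fraction = 1, n = 5e4)
  early <- coh2[coh2$d < 0.02, ]
  expect_gt(nrow(early), 50)
  expect_equal(mean(early$p), exp(1.96 + 0.27^2 / 2) + 3.6, tolerance = 0.15)
})

test_that("prolonged cohorts show the negative phase-length trend in d", {
  pp <- nci_params()
  set.seed(402)
  coh <- build_virtual_cohort(3.6, "G1", pp, list(mu_d = 1, sigma_d = 0.39),
                              surviving_fraction = 0.25, n = 1e5)
  early_d <- coh[coh$d >= 0 & coh$d < 4, ]
  slope <- coef(lm(p ~ d, data = early_d))[2]
  expect_lt(slope, 0)
})

test_that("the z likelihood is minimized near the generating value and stays finite", {
  pp <- nci_params()
  set.seed(403)
  truth <- build_virtual_cohort(3, "G1", pp, list(mu_d = 1, sigma_d = 0.39),
                                surviving_fraction = 0.25, n = 3e4)
  pairs <- truth[sample.int(nrow(truth), 500), c("d", "p")]
  nll <- vapply(c(0, 3, 6), function(z) {
    negll_for_z(z, pairs, "G1", pp, list(mu_d = 1, sigma_d = 0.39),
                surviving_fraction = 0.25, cohort_size = 5e4)
  }, numeric(1))
  expect_lt(nll[2], nll[1])
  expect_lt(nll[2], nll[3])
  # a d value without cohort support triggers adaptive widening, not -Inf
  odd <- data.frame(d = 30, p = 35)
  v <- negll_for_z(0, odd, "G1", pp, list(mu_d = 1, sigma_d = 0.39),
                   surviving_fraction = 0.25, cohort_size = 2e4)
  expect_true(is.finite(v))
  expect_gte(attr(v, "n_widened_bins"), 1)
})

test_that("negative log-likelihood is stable in the cohort size", {
  pp <- nci_params()
  set.seed(404)
  coh <- build_virtual_cohort(2, "G1", pp, list(mu_d = 1, sigma_d = 0.39),
                              surviving_fraction = 0.25, n = 2e4)
  pairs <- coh[sample.int(nrow(coh), 300), c("d", "p")]
  v_small <- replicate(6, negll_for_z(2, pairs, "G1", pp,
                                      list(mu_d = 1, sigma_d = 0.39), 0.25,
                                      cohort_size = 2e4))
  v_big <- replicate(6, negll_for_z(2, pairs, "G1", pp,
                                    list(mu_d = 1, sigma_d = 0.39), 0.25,
                                    cohort_size = 4e4))
  expect_lt(abs(mean(v_big) - mean(v_small)), 3 * sd(v_small) + 1)
})

test_that("z is recovered from tracks at moderate scale", {
  set.seed(405)
  cfg <- experiment_config(n_cells = 3000, z_true = 2)
  tr <- simulate_tracks(cfg, seed = 405)
  ze <- estimate_z_from_tracks(tr, "G1", z_grid = seq(0, 6, 0.25),
                               n_reps = 3, cohort_size = 4e4, seed = 4051)
  expect_equal(ze$z_hat, 2, tolerance = 0.5)
  expect_false(ze$on_boundary)
  # polynomial smooth leaves no structure: residuals uncorrelated with z
  td <- tidy(ze)
  expect_gt(cor.test(td$z, td$negll_mean - td$negll_poly)$p.value, 0.01)
  g <- glance(ze)
  expect_true(g$ci_low <= ze$z_hat && ze$z_hat <= g$ci_high)
})

test_that("the prolongation appears as the mean phase-length shift when deaths vanish", {
  pp <- nci_params()
  set.seed(406)
  # closed-form limit: E[p] - E[T] = z E[1 - d/T] -> z * E over the cohort;
  # with no deaths and d = frac * T, E[p - T] = z * (1 - E[frac])
  coh <- build_virtual_cohort(3.6, "G1", pp, list(mu_d = 20, sigma_d = 0.1),
                              surviving_fraction = 0, n = 1e5)
  # steady-state mean within-phase fraction on G1
  fbar <- integrate(function(c) (c / 0.45) * 2^(1 - c) * log(2) /
                      (2 - 2^(1 - 0.45)), 0, 0.45)$value
  T_native <- suppressWarnings(as.numeric(
    invert_phase_length(coh$p, coh$d, 3.6)))
  expect_equal(mean(coh$p - T_native), 3.6 * (1 - fbar), tolerance = 0.05)
})
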