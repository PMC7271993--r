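test_that("closed-form death times match hand-derived cases", {
  r <- growth_rates(7.4, 9.0)
  # threshold reached before any deceleration: t = 1/m
  expect_equal(death_time(0, r, 0.4, 0.2, 0.52), 2.5)
  # p = 0 decouples death from the cycle entirely
  for (c0 in c(0.1, 0.5, 0.9)) {
    expect_equal(death_time(c0, r, 0.4, 0, 0.3), 2.5)
  }
  # decelerated from the start, death before division
  expect_equal(death_time(0.6, r, 0.4, 0.2, 0.52), 5)
  # floored progression: stalls until division, then dies at slope m
  expect_equal(death_time(0.7, r, 0.15, 0.2, 0.52),
               (1 - 0.7) / (0.55 / 9.0) + 1 / 0.15, tolerance = 1e-9)
})

test_that("death times agree with the forward-Euler oracle in both variants", {
  set.seed(601)
  n <- 150
  for (variant in c("release_at_division", "extended_second_generation")) {
    r <- random_rates(n)
    c0 <- runif(n, 0, 0.999)
    m <- 1 / rlnorm(n, 1, 0.39)
    p <- runif(1, 0.05, 0.35)
    pad <- runif(1, 0.3, 0.9)
    td <- death_time(c0, r, m, p, pad, variant)
    ref <- euler_death_time(c0, r$g_g1, r$g_s, r$g_g1_f1, r$g_s_f1, 0.45,
                            m, p, pad, variant)
    ok <- !is.na(ref)
    expect_gt(mean(ok), 0.5)
    expect_lt(max(abs(td[ok] - ref[ok])), 1e-3)
  }
})

test_that("death times are monotone in the deceleration and the slope", {
  set.seed(602)
  n <- 300
  r <- random_rates(n)
  c0 <- runif(n, 0, 0.999)
  m <- 1 / rlnorm(n, 1, 0.39)
  td_base <- death_time(c0, r, m, 0.1, 0.52)
  td_more_p <- death_time(c0, r, m, 0.2, 0.52)
  td_more_m <- death_time(c0, r, m * 1.5, 0.1, 0.52)
  expect_true(all(td_more_p >= td_base - 1e-12))
  expect_true(all(td_more_m <= td_base + 1e-12))
})

test_that("cells treated just before mitosis fall back to the fast-death regime", {
  r <- growth_rates(7.4, 9.0)
  m <- 0.4
  c0 <- 0.999
  td <- death_time(c0, r, m, 0.3, 0.52)
  # remaining decelerated stretch is negligible: t ~ (1 - c0)/g_s + 1/m
  expect_equal(td, (1 - c0) / (0.55 / 9.0) + 1 / m, tolerance = 0.05)
})

test_that("slope draws and p = 0 death times match the early-G1 calibration", {
  set.seed(603)
  m <- 1 / rlnorm(1e6, 1, 0.39)
  expect_equal(mean(m), exp(-1 + 0.39^2 / 2), tolerance = 0.001)
  # printed to one decimal this is the 0.4 /h mean slope
  expect_equal(round(mean(m), 1), 0.4)
  pp <- nci_params()
  coh <- simulate_death_cohort(5e4, pp, apoptosis_params(p = 0),
                               horizon = Inf)
  expect_true(all(coh$died))
  # with p = 0, t_death = 1/m is exactly lognormal(1, 0.39), mean 2.9 h
  expect_equal(mean(coh$t_death), exp(1 + 0.39^2 / 2), tolerance = 0.02)
  ks <- suppressWarnings(ks.test(coh$t_death, plnorm, 1, 0.39))
  expect_gt(ks$p.value, 0.01)
})

test_that("cells just below the deceleration point split into two death-time modes", {
  pp <- nci_params()
  set.seed(604)
  coh <- simulate_death_cohort(3e4, pp,
                               apoptosis_params(p = 0.3, pad = 0.52),
                               c0_scheme = "window", window = c(0.47, 0.52),
                               horizon = Inf)
  td <- coh$t_death
  frac_fast <- mean(td < 4)
  frac_slow <- mean(td > 9)
  frac_valley <- mean(td >= 6 & td <= 8)
  expect_gt(frac_fast, 0.15)
  expect_gt(frac_slow, 0.15)
  expect_lt(frac_valley, frac_fast)
  expect_lt(frac_valley, frac_slow)
})

test_that("the KDE likelihood matches a direct kernel sum and floors outliers", {
  pp <- nci_params()
  set.seed(605)
  coh <- simulate_death_cohort(2000, pp, apoptosis_params())
  coh <- coh[coh$died, c("c0", "t_death")]
  tup <- coh[sample.int(nrow(coh), 50), ]
  v <- negll_pad(tup, coh, gridsize = 400)
  # direct Gaussian product-kernel evaluation (same Silverman bandwidths)
  bx <- bw.nrd0(coh$c0); by <- bw.nrd0(coh$t_death)
  dens <- vapply(seq_len(nrow(tup)), function(i) {
    mean(dnorm(tup$c0[i], coh$c0, bx) * dnorm(tup$t_death[i], coh$t_death, by))
  }, numeric(1))
  expect_equal(v, -sum(log(pmax(dens, 1e-9))), tolerance = 0.01)
  # a far-away tuple contributes exactly -ln(1e-9)
  far <- rbind(tup, data.frame(c0 = 0.5, t_death = 500))
  expect_equal(negll_pad(far, coh, gridsize = 400) - v, -log(1e-9),
               tolerance = 1e-6)
  # permutation invariance
  expect_equal(negll_pad(tup[sample.int(50), ], coh, gridsize = 400), v)
  # degenerate cohorts are rejected
  degen <- data.frame(c0 = rep(0.5, 1500), t_death = rep(3, 1500))
  expect_error(negll_pad(tup, degen), "degenerate")
})

test_that("pad is structurally unidentifiable when p = 0", {
  pp <- nci_params()
  set.seed(606)
  coh <- simulate_death_cohort(4000, pp, apoptosis_params(p = 0))
  tup <- coh[coh$died, c("c0", "t_death")][1:400, ]
  est <- estimate_pad(tup, pp, p_grid = c(0, 0.1, 0.2),
                      pad_grid = c(0.4, 0.6, 0.8),
                      n_reps = 2, cohort_size = 5e3)
  # the entire pad axis lies inside the joint region at p = 0
  expect_true(all(pad_region_contains(est, rep(0, 3), c(0.4, 0.6, 0.8))))
})

test_that("synchronization windows are exchangeable when death ignores the cycle", {
  pp <- nci_params()
  set.seed(607)
  sw <- synchronization_sweep(lapply(c(0, 0.3, 0.6, 0.9), function(a)
    c(a, a + 0.1)), pp, apoptosis_params(p = 0), n_per_window = 5000, z = 0)
  expect_lt(diff(range(sw$median_t_death)), 0.15)
  expect_lt(diff(range(sw$iqr_t_death)), 0.2)
})

test_that("mean progression trajectories have the prescribed slopes and stay in [0, 1]", {
  r <- growth_rates(7.4, 9.0)
  tr <- mean_progression_curve(0.2, r, 0.12, 0.05, 0.52)
  slopes <- diff(tr$a) / diff(tr$t)
  # before the deceleration point: slope m; after: m - p
  expect_equal(slopes[1], 0.12, tolerance = 1e-9)
  decel_seg <- which(tr$c[-nrow(tr)] >= 0.52 & tr$c[-1] <= 1)
  expect_equal(unique(round(slopes[decel_seg], 9)), 0.12 - 0.05)
  expect_true(all(tr$a >= 0 & tr$a <= 1 + 1e-12))
  # non-decreasing whenever m >= p
  expect_true(all(diff(tr$a) >= -1e-12))
  expect_equal(tr$a[nrow(tr)], 1)
})
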