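test_that("steady-state position sampler matches the analytic distribution", {
  # inverse CDF: closed-form spot values
  expect_equal(1 - log2(2 - 0), 0)
  set.seed(101)
  x <- sample_initial_positions(1e5, "steady_state")
  expect_true(all(x >= 0 & x < 1))
  # KS distance against F(c) = 2 - 2^(1 - c)
  ks <- max(abs(ecdf(x)(sort(x)) - (2 - 2^(1 - sort(x)))))
  expect_lt(ks, 0.01)
  # median of the distribution is 1 - log2(1.5)
  expect_equal(median(x), 1 - log2(1.5), tolerance = 0.01)
  # density integrates to 1
  expect_equal(integrate(function(c) 2^(1 - c) * log(2), 0, 1)$value, 1,
               tolerance = 1e-8)
})

test_that("windowed and uniform sampling schemes respect their bounds", {
  set.seed(102)
  w <- sample_initial_positions(2000, "window", window = c(0.3, 0.4))
  expect_true(all(w >= 0.3 & w <= 0.4))
  s <- sample_initial_positions(2000, "steady_state", window = c(0, 0.45))
  expect_true(all(s < 0.45))
  expect_error(sample_initial_positions(10, "window", window = c(0.5, 0.2)),
               "window")
  expect_identical(sample_initial_positions(0), numeric(0))
})

test_that("phase-duration sampling reproduces the configured moments", {
  set.seed(103)
  pp <- phase_params(1.96, 0.27, 2.18, 0.19, rho_log = 0)
  d <- sample_phase_durations(2e5, pp)
  expect_equal(mean(d$t_g1), exp(1.96 + 0.27^2 / 2), tolerance = 0.01)
  expect_equal(mean(d$t_s), exp(2.18 + 0.19^2 / 2), tolerance = 0.01)
  expect_lt(abs(cor(log(d$t_g1), log(d$t_s))), 0.01)
  # correlated draws hit the requested duration-scale correlation
  rho <- rho_log_for_duration_corr(0.33, 0.27, 0.19)
  d2 <- sample_phase_durations(2e5, phase_params(1.96, 0.27, 2.18, 0.19,
                                                 rho_log = rho))
  expect_equal(cor(d2$t_g1, d2$t_s), 0.33, tolerance = 0.015)
})

test_that("advance_position handles boundaries and matches a fine-step integrator", {
  r <- growth_rates(7.4, 9.0)
  expect_equal(advance_position(0.2, 0, r), 0.2)
  expect_equal(advance_position(0, 7.4, r), 0.45)
  # crossing the G1/S boundary mid-way
  expect_equal(advance_position(0.40, 2, r),
               0.45 + (2 - 0.05 / (0.45 / 7.4)) * (0.55 / 9.0),
               tolerance = 1e-9)
  set.seed(104)
  for (i in 1:20) {
    rr <- random_rates(1)
    c0 <- runif(1, 0, 0.9)
    t <- runif(1, 0, 15)
    ref <- step_advance(c0, t, rr$g_g1, rr$g_s, rr$g_g1_f1, rr$g_s_f1, 0.45)
    if (ref < 2) {
      expect_equal(advance_position(c0, t, rr), ref, tolerance = 1e-4)
    }
  }
})

test_that("corrected growth rate implements the prolongation map", {
  g <- 0.45 / 7.4
  expect_equal(corrected_growth_rate(g, 0.45, 0), g)
  expect_equal(corrected_growth_rate(g, 0.45, 3.6), 0.45 / 11.0)
  expect_lt(corrected_growth_rate(g, 0.45, 1e9), 1e-9)
})

test_that("phase length under TRAIL is prolonged more the earlier the exposure", {
  expect_equal(phase_length_under_trail(7.4, 0, 3.6), 7.4 + 3.6)
  expect_equal(phase_length_under_trail(7.4, 7.4, 3.6), 7.4)
  expect_equal(phase_length_under_trail(7.4, 3.7, 3.6), 9.2)
  expect_equal(phase_length_under_trail(7.4, 0, 3.6, "whole_phase"), 11)
  expect_equal(phase_length_under_trail(7.4, 7.4, 3.6, "whole_phase"), 11)
  # strictly decreasing in d for fixed T in post-exposure mode
  d <- seq(0, 7.4, length.out = 50)
  p <- phase_length_under_trail(7.4, d, 3.6)
  expect_true(all(diff(p) < 0))
  expect_error(phase_length_under_trail(7.4, 8, 3.6), "exceed")
})

test_that("phase-length inversion round-trips the forward map exactly", {
  expect_equal(as.numeric(invert_phase_length(9.2, 3.7, 3.6)), 7.4,
               tolerance = 1e-12)
  expect_equal(as.numeric(invert_phase_length(9.2, 3.7, 0)), 9.2)
  expect_equal(as.numeric(invert_phase_length(9.2, 0, 3.6)), 9.2 - 3.6)
  set.seed(105)
  for (mode in c("post_exposure", "whole_phase")) {
    T0 <- runif(200, 2, 20)
    d <- runif(200) * T0
    z <- runif(200, 0, 6)
    p <- phase_length_under_trail(T0, d, z, mode)
    keep <- p > d & (mode != "whole_phase" | p > z + d)
    T1 <- suppressWarnings(
      invert_phase_length(p[keep], d[keep], z[keep], mode))
    expect_lt(max(abs(as.numeric(T1) - T0[keep])), 1e-9)
  }
  # degenerate whole-phase input is clipped and flagged
  expect_warning(out <- invert_phase_length(3, 2.5, 1, "whole_phase"),
                 "clipped")
  expect_true(attr(out, "clipped"))
  expect_gt(as.numeric(out), 2.5)
})
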