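# Independent brute-force oracles used to cross-check the closed-form
# implementations. These deliberately share no code with the package
# internals: positions advance by explicit small-step integration and the
# apoptosis level by forward Euler.

nci_params <- function() cell_line_preset("NCI-H460")$phase_params

# Fine-step integrator for the piecewise-linear cycle coordinate.
step_advance <- function(c0, t, g_g1, g_s, g_g1_f1, g_s_f1, f, dt = 2e-4) {
  C <- c0
  steps <- round(t / dt)
  for (i in seq_len(steps)) {
    g <- if (C < f) g_g1 else if (C < 1) g_s else if (C < 1 + f) g_g1_f1 else g_s_f1
    C <- C + g * dt
  }
  C + (t - steps * dt) * (if (C < f) g_g1 else if (C < 1) g_s else
                          if (C < 1 + f) g_g1_f1 else g_s_f1)
}

# Forward-Euler oracle for PAD-model death times, vectorized over cells.
euler_death_time <- function(c0, g_g1, g_s, g_g1_f1, g_s_f1, f, m, p, pad,
                             variant = "release_at_division",
                             dt = 1e-4, t_max = 40) {
  n <- length(c0)
  g_g1 <- rep_len(g_g1, n); g_s <- rep_len(g_s, n)
  g_g1_f1 <- rep_len(g_g1_f1, n); g_s_f1 <- rep_len(g_s_f1, n)
  m <- rep_len(m, n)
  ext <- variant == "extended_second_generation"
  C <- c0
  A <- numeric(n)
  td <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  t <- 0
  while (any(alive) && t < t_max) {
    g <- ifelse(C < f, g_g1,
         ifelse(C < 1, g_s,
         ifelse(C < 1 + f, g_g1_f1, g_s_f1)))
    decel <- (C > pad & C < 1) | (ext & C > 1 + pad & C < 2)
    s <- m - p * decel
    Anew <- pmax(0, A + s * dt)
    hit <- alive & Anew >= 1
    # sub-step linear interpolation of the crossing
    td[hit] <- t + (1 - A[hit]) / s[hit]
    alive <- alive & !hit
    A <- Anew
    C <- C + g * dt
    t <- t + dt
  }
  td
}

# Random growth-rates fixture (two generations, plausible duration ranges).
random_rates <- function(n, f = 0.45) {
  growth_rates(runif(n, 4, 15), runif(n, 5, 16),
               runif(n, 4, 15), runif(n, 5, 16), f_g1 = f)
}

# Hand-written right-censored lognormal log-likelihood, maximized by optim:
# the independent route against fitdistrplus.
censored_lnorm_mle <- function(values, censored) {
  nll <- function(par) {
    mu <- par[1]; sg <- exp(par[2])
    -sum(dlnorm(values[!censored], mu, sg, log = TRUE)) -
      sum(plnorm(values[censored], mu, sg, lower.tail = FALSE, log.p = TRUE))
  }
  fit <- optim(c(mean(log(values)), log(sd(log(values)))), nll)
  c(meanlog = fit$par[1], sdlog = exp(fit$par[2]), nll = fit$value)
}
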