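#' Lognormal phase-duration parameters
#'
#' Bundles the log-scale parameters of the lognormal G1 and S/G2/M phase
#' duration distributions together with the phase-boundary fractions of the
#' normalized cell-cycle coordinate. On that coordinate, G1 occupies
#' `[0, f_g1)`, S/G2/M occupies `[f_g1, 1)`, division happens at 1 and
#' `[1, 2)` repeats the layout for the daughter generation.
#'
#' @param mu_g1,sigma_g1 Log-scale mean and sd (log-hours) of G1 durations.
#' @param mu_s,sigma_s Log-scale mean and sd (log-hours) of S/G2/M durations.
#' @param f_g1 Fraction of the cycle occupied by G1 (default 0.45, the
#'   NCI-H460 value; S/G2/M gets `1 - f_g1`).
#' @param rho_log Correlation of the two log-durations in `[-1, 1]`.
#'
#' @return A `phase_params` list with fields `mu_g1`, `sigma_g1`, `mu_s`,
#'   `sigma_s`, `f_g1`, `f_s`, `rho_log`.
#' @examples
#' pp <- phase_params(1.96, 0.27, 2.18, 0.19)
#' implied_phase_means(pp) # 7.4 h and 9.0 h
#' @export
phase_params <- function(mu_g1, sigma_g1, mu_s, sigma_s,
                         f_g1 = 0.45, rho_log = 0) {
  stopifnot(sigma_g1 > 0, sigma_s > 0,
            f_g1 > 0, f_g1 < 1,
            rho_log >= -1, rho_log <= 1)
  structure(
    list(mu_g1 = mu_g1, sigma_g1 = sigma_g1,
         mu_s = mu_s, sigma_s = sigma_s,
         f_g1 = f_g1, f_s = 1 - f_g1, rho_log = rho_log),
    class = "phase_params"
  )
}

#' @export
print.phase_params <- function(x, ...) {
  m <- implied_phase_means(x)
  cat("Phase-duration parameters (lognormal):\n")
  cat(sprintf("  G1:     mu = %.3f, sigma = %.3f  (mean %.2f h), f = %.2f\n",
              x$mu_g1, x$sigma_g1, m$mean_g1, x$f_g1))
  cat(sprintf("  S/G2/M: mu = %.3f, sigma = %.3f  (mean %.2f h), f = %.2f\n",
              x$mu_s, x$sigma_s, m$mean_s, x$f_s))
  cat(sprintf("  log-duration correlation: %.3f\n", x$rho_log))
  invisible(x)
}

#' Implied mean phase durations
#'
#' Closed-form lognormal means `exp(mu + sigma^2/2)` for both phases, the
#' mean total cycle time and the G1 share of it.
#'
#' @param params A [phase_params()] object.
#' @return A tibble with `mean_g1`, `mean_s`, `mean_cycle` (hours) and
#'   `g1_fraction` (mean G1 duration over mean cycle duration).
#' @export
implied_phase_means <- function(params) {
  m1 <- exp(params$mu_g1 + params$sigma_g1^2 / 2)
  m2 <- exp(params$mu_s + params$sigma_s^2 / 2)
  tibble::tibble(mean_g1 = m1, mean_s = m2,
                 mean_cycle = m1 + m2,
                 g1_fraction = m1 / (m1 + m2))
}

#' Log-scale correlation matching a target duration-scale correlation
#'
#' For a bivariate lognormal pair with log-sds `sigma1`, `sigma2`, returns the
#' correlation of the underlying normals that yields a Pearson correlation
#' `target` between the durations themselves.
#'
#' @param target Desired Pearson correlation of the durations.
#' @param sigma1,sigma2 Log-scale standard deviations.
#' @return Scalar log-scale correlation.
#' @export
rho_log_for_duration_corr <- function(target, sigma1, sigma2) {
  stopifnot(abs(target) < 1)
  log(1 + target * sqrt(expm1(sigma1^2) * expm1(sigma2^2))) / (sigma1 * sigma2)
}

## Steady-state position distribution: density 2^(1 - c) * ln 2 on [0, 1),
## CDF F(c) = 2 - 2^(1 - c), inverse c = 1 - log2(2 - u).
steady_state_cdf <- function(c) 2 - 2^(1 - c)

steady_state_quantile <- function(u) 1 - log2(2 - u)

#' Sample initial cell-cycle positions
#'
#' Draws positions on the normalized cycle coordinate `[0, 1)`. The default
#' scheme is the steady-state age distribution of an exponentially growing,
#' unsynchronized population, with density `2^(1 - c) ln 2`; young cells are
#' over-represented because every division produces two newborns. The
#' `"uniform"` scheme draws standard-uniform positions and `"window"` draws
#' uniformly inside `window = c(a, b)` (used for synchronization scenarios).
#' For `"steady_state"` a `window` restricts (renormalizes) the steady-state
#' density to that interval.
#'
#' @param n Number of draws.
#' @param scheme One of `"steady_state"`, `"uniform"`, `"window"`.
#' @param window Length-2 numeric `c(a, b)` with `0 <= a < b <= 1`.
#' @return Numeric vector of length `n` in `[0, 1)`.
#' @export
sample_initial_positions <- function(n,
                                     scheme = c("steady_state", "uniform", "window"),
                                     window = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 0)
  if (!is.null(window)) {
    if (length(window) != 2 || window[1] < 0 || window[2] > 1 ||
        window[1] >= window[2]) {
      stop("`window` must be c(a, b) with 0 <= a < b <= 1", call. = FALSE)
    }
  }
  if (n == 0) return(numeric(0))
  switch(scheme,
    uniform = stats::runif(n),
    window = {
      if (is.null(window)) stop("scheme 'window' requires `window`", call. = FALSE)
      stats::runif(n, window[1], window[2])
    },
    steady_state = {
      if (is.null(window)) {
        steady_state_quantile(stats::runif(n))
      } else {
        lo <- steady_state_cdf(window[1])
        hi <- steady_state_cdf(window[2])
        steady_state_quantile(stats::runif(n, lo, hi))
      }
    }
  )
}

#' Sample correlated lognormal phase-duration pairs
#'
#' Draws `(T_G1, T_SG2M)` pairs whose logs are bivariate normal with the
#' marginal parameters and log-scale correlation of `params`.
#'
#' @param n Number of pairs.
#' @param params A [phase_params()] object.
#' @return A tibble with columns `t_g1`, `t_s` (hours).
#' @export
sample_phase_durations <- function(n, params) {
  stopifnot(n >= 0)
  if (n == 0) return(tibble::tibble(t_g1 = numeric(0), t_s = numeric(0)))
  rho <- params$rho_log
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  tibble::tibble(
    t_g1 = exp(params$mu_g1 + params$sigma_g1 * z1),
    t_s  = exp(params$mu_s + params$sigma_s * z2)
  )
}

#' Per-cell growth rates on the cycle coordinate
#'
#' Converts sampled phase durations into piecewise-constant progression rates
#' of the cycle coordinate: a cell in G1 advances at `f_g1 / T_G1` cycle
#' fractions per hour, so that traversing G1 takes exactly `T_G1` hours.
#' Daughter-generation durations are supplied separately (they are resampled
#' independently at each phase entry).
#'
#' @param t_g1,t_s Mother-generation phase durations (hours); vectors recycle.
#' @param t_g1_f1,t_s_f1 Daughter-generation durations; default to the mother
#'   values.
#' @param f_g1 G1 fraction of the cycle coordinate.
#' @return A `growth_rates` list of vectors `g_g1`, `g_s`, `g_g1_f1`,
#'   `g_s_f1` (cycle fraction per hour) and the scalar `f_g1`.
#' @export
growth_rates <- function(t_g1, t_s, t_g1_f1 = t_g1, t_s_f1 = t_s, f_g1 = 0.45) {
  stopifnot(all(t_g1 > 0), all(t_s > 0), all(t_g1_f1 > 0), all(t_s_f1 > 0))
  structure(
    list(g_g1 = f_g1 / t_g1, g_s = (1 - f_g1) / t_s,
         g_g1_f1 = f_g1 / t_g1_f1, g_s_f1 = (1 - f_g1) / t_s_f1,
         f_g1 = f_g1),
    class = "growth_rates"
  )
}

#' Advance a cycle position for a given time
#'
#' Moves positions forward on the cycle coordinate with piecewise-linear
#' motion: the rate in each interval (`[0, f_g1)`, `[f_g1, 1)`, and their
#' daughter-generation counterparts) is the phase-specific per-cell rate.
#' Motion is continuous across phase boundaries and division.
#'
#' @param c0 Starting positions in `[0, 2)`.
#' @param t Elapsed time in hours (`>= 0`); recycled against `c0`.
#' @param rates A [growth_rates()] object (vector fields recycle).
#' @return Numeric vector of positions; capped at 2 (one full daughter
#'   generation) with a warning if the horizon is exceeded.
#' @export
advance_position <- function(c0, t, rates) {
  stopifnot(all(t >= 0), all(c0 >= 0), all(c0 < 2))
  f <- rates$f_g1
  n <- max(length(c0), length(t), length(rates$g_g1), length(rates$g_s))
  c_cur <- rep_len(c0, n)
  t_rem <- rep_len(t, n)
  lower <- c(0, f, 1, 1 + f)
  upper <- c(f, 1, 1 + f, 2)
  gl <- list(rep_len(rates$g_g1, n), rep_len(rates$g_s, n),
             rep_len(rates$g_g1_f1, n), rep_len(rates$g_s_f1, n))
  for (k in 1:4) {
    dist <- pmax(0, upper[k] - pmax(c_cur, lower[k]))
    need <- dist / gl[[k]]
    dt <- pmin(need, t_rem)
    c_cur <- c_cur + dt * gl[[k]] * (dist > 0)
    t_rem <- t_rem - dt * (dist > 0)
  }
  if (any(t_rem > 1e-12)) {
    warning("some cells advanced beyond the simulated two-generation horizon; capped at 2")
    c_cur <- pmin(c_cur, 2)
  }
  c_cur
}

#' TRAIL-corrected growth rate
#'
#' Applies the phenomenological phase prolongation: a phase that would take
#' `f/g` hours takes `f/g + z` hours under TRAIL, so the corrected rate is
#' `f / (f/g + z)`.
#'
#' @param g Native rate (cycle fraction per hour, `> 0`).
#' @param f Phase fraction in `(0, 1)`.
#' @param z Prolongation in hours (`>= 0`).
#' @return Corrected rate; equals `g` when `z = 0`.
#' @export
corrected_growth_rate <- function(g, f, z) {
  stopifnot(all(g > 0), all(f > 0), all(f < 1), all(z >= 0))
  f / (f / g + z)
}

#' Total phase length under TRAIL exposure
#'
#' Length of a phase for a cell treated `d` hours after entering a phase of
#' native length `T`. In `post_exposure` mode only the remaining part of the
#' phase is slowed (the pre-treatment part ran at the native rate), giving
#' `p = T + z - d z / T`: the earlier in the phase a cell is exposed, the
#' larger the prolongation, and `p` is strictly decreasing in `d` for fixed
#' `T`. In `whole_phase` mode the entire phase is stretched: `p = T + z`.
#'
#' @param T_phase Native phase length (hours).
#' @param d Time already spent in the phase at treatment (`0 <= d <= T`).
#' @param z Prolongation (hours, `>= 0`).
#' @param mode `"post_exposure"` (default) or `"whole_phase"`.
#' @return Total phase length `p` in hours.
#' @export
phase_length_under_trail <- function(T_phase, d, z,
                                     mode = c("post_exposure", "whole_phase")) {
  mode <- match.arg(mode)
  stopifnot(all(z >= 0), all(d >= 0))
  if (any(d > T_phase + 1e-12)) {
    stop("`d` must not exceed the native phase length", call. = FALSE)
  }
  if (mode == "whole_phase") {
    T_phase + z - 0 * d
  } else {
    T_phase + z - d * z / T_phase
  }
}

#' Invert the TRAIL phase-length map
#'
#' Recovers the native phase length `T` from an observed prolonged length
#' `p`, the time of exposure `d` and a prolongation `z`. In `post_exposure`
#' mode `T` is the positive root of `T^2 + (z - p) T - d z = 0`; in
#' `whole_phase` mode `T = p - z`. The result is clipped to `T > d`
#' (degenerate inputs return `d * (1 + 1e-6)` and are flagged via the
#' `"clipped"` attribute).
#'
#' @inheritParams phase_length_under_trail
#' @param p Observed total phase length (hours, `p > d`).
#' @return Native length `T` (hours), with a logical `"clipped"` attribute.
#' @export
invert_phase_length <- function(p, d, z,
                                mode = c("post_exposure", "whole_phase")) {
  mode <- match.arg(mode)
  stopifnot(all(z >= 0), all(d >= 0), all(p > d))
  T_est <- if (mode == "whole_phase") {
    (p - z) + 0 * d
  } else {
    ((p - z) + sqrt((p - z)^2 + 4 * d * z)) / 2
  }
  n <- length(T_est)
  dd <- rep_len(d, n)
  clipped <- T_est <= dd
  if (any(clipped)) {
    warning(sum(clipped), " inverted phase length(s) clipped to T > d")
    T_est[clipped] <- dd[clipped] * (1 + 1e-6)
  }
  attr(T_est, "clipped") <- clipped
  T_est
}
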