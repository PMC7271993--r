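#' Parameters of the point-of-apoptosis-deceleration (PAD) model
#'
#' Apoptosis progression `A(t)` rises from 0 with a per-cell slope `m`
#' (1/hours) and the cell dies when `A` reaches 1. While the cell-cycle
#' coordinate lies beyond the deceleration point `pad` (but before division),
#' the slope drops to `m - p`; `A` is floored at 0, so cells with `m <= p`
#' stall until the brake is released. Under `release_at_division` the brake
#' is removed once the cell divides; under `extended_second_generation` it
#' re-engages in the daughter generation beyond coordinate `1 + pad`.
#' Per-cell slopes are drawn as the reciprocal of a lognormal draw so that
#' `1/m` matches the death-time distribution of early-G1 cells.
#'
#' @param mu_td,sigma_td Log-scale parameters of the early-G1 death-time
#'   lognormal; `m = 1 / lognormal(mu_td, sigma_td)` (defaults 1 and 0.39,
#'   giving mean death time 2.9 h and mean slope 0.4 /h).
#' @param p Population-level deceleration (1/hours, `>= 0`).
#' @param pad Deceleration point on the cycle coordinate, in `[0, 1]`.
#' @param variant `"release_at_division"` or `"extended_second_generation"`.
#' @return An `apoptosis_params` list.
#' @export
apoptosis_params <- function(mu_td = 1, sigma_td = 0.39,
                             p = 0.2, pad = 0.52,
                             variant = c("release_at_division",
                                         "extended_second_generation")) {
  variant <- match.arg(variant)
  stopifnot(sigma_td > 0, p >= 0, pad >= 0, pad <= 1)
  structure(list(mu_td = mu_td, sigma_td = sigma_td,
                 p = p, pad = pad, variant = variant),
            class = "apoptosis_params")
}

## Closed-form piecewise-linear death times for a vector of cells.
## Breakpoints of A(t)'s slope occur where C crosses pad, the phase
## boundaries, division (C = 1) and, for the extended variant, 1 + pad.
pad_death_times <- function(c0, rates, m, p, pad,
                            variant = c("release_at_division",
                                        "extended_second_generation")) {
  variant <- match.arg(variant)
  f <- rates$f_g1
  n <- length(c0)
  g <- list(rep_len(rates$g_g1, n), rep_len(rates$g_s, n),
            rep_len(rates$g_g1_f1, n), rep_len(rates$g_s_f1, n))
  m <- rep_len(m, n)
  ext <- variant == "extended_second_generation"
  thr <- sort(unique(c(f, pad, 1, 1 + f, if (ext) 1 + pad, 2)))
  thr <- thr[thr > 0 & thr <= 2]
  bnd <- c(0, f, 1, 1 + f, 2)
  time_to <- function(ct) {
    tt <- numeric(n)
    for (k in 1:4) {
      seg <- pmax(0, pmin(ct, bnd[k + 1]) - pmax(c0, bnd[k]))
      tt <- tt + seg / g[[k]]
    }
    tt
  }
  arrive <- vapply(thr, time_to, numeric(n))
  if (n == 1) arrive <- matrix(arrive, nrow = 1)
  gthr <- c(0, thr)
  A <- numeric(n)
  td <- rep(NA_real_, n)
  t_prev <- numeric(n)
  for (j in seq_along(thr)) {
    mid <- (gthr[j] + gthr[j + 1]) / 2
    decel <- (mid > pad && mid < 1) || (ext && mid > 1 + pad && mid < 2)
    s <- m - (if (decel) p else 0)
    t_end <- arrive[, j]
    dur <- pmax(0, t_end - t_prev)
    alive <- is.na(td)
    hit <- alive & s > 0 & (A + s * dur >= 1)
    td[hit] <- t_prev[hit] + (1 - A[hit]) / s[hit]
    upd <- alive & !hit
    A[upd] <- pmax(0, A[upd] + s[upd] * dur[upd])
    t_prev <- t_end
  }
  alive <- is.na(td)
  td[alive] <- t_prev[alive] + (1 - A[alive]) / m[alive]
  list(t_death = td, t_division = time_to(1))
}

#' Death time under the PAD model
#'
#' Closed-form solution of the piecewise-linear apoptosis-progression
#' trajectory for cells starting at cycle positions `c0` with per-cell rates
#' and slopes. See [apoptosis_params()] for the model.
#'
#' @param c0 Initial cycle positions in `[0, 1)`.
#' @param rates A [growth_rates()] object.
#' @param m Per-cell apoptosis slopes (1/hours, `> 0`).
#' @param p Deceleration (1/hours, `>= 0`).
#' @param pad Deceleration point in `[0, 1]`.
#' @param variant Model variant, see [apoptosis_params()].
#' @param horizon Observation horizon in hours; deaths later than this are
#'   returned as `NA`.
#' @return Numeric vector of death times (hours), `NA` where no death occurs
#'   within the horizon.
#' @export
death_time <- function(c0, rates, m, p, pad,
                       variant = c("release_at_division",
                                   "extended_second_generation"),
                       horizon = Inf) {
  stopifnot(all(c0 >= 0), all(c0 < 1), all(m > 0), p >= 0,
            pad >= 0, pad <= 1)
  td <- pad_death_times(c0, rates, m, p, pad, variant)$t_death
  td[td > horizon] <- NA_real_
  td
}

#' Simulate a virtual death-time cohort
#'
#' Draws a virtual cell population (cycle positions, per-phase growth rates
#' for two generations, apoptosis slopes) and computes PAD-model death times.
#'
#' @param n Number of cells.
#' @param phase_params A [phase_params()] object.
#' @param apoptosis A [apoptosis_params()] object.
#' @param c0_scheme Position sampling scheme, see [sample_initial_positions()].
#' @param window Optional window for the sampling scheme.
#' @param horizon Observation horizon (hours, default 19.25, the length of
#'   the post-treatment imaging window).
#' @param z Optional TRAIL-induced phase prolongation (hours) applied to the
#'   cycle kinematics of the cohort (all phase durations stretched by `z`);
#'   default 0, i.e. death kinetics run on the native rates.
#' @return A tibble with `c0`, `m`, `t_death`, `t_division`,
#'   `divided_before_death` and `died` (death within the horizon); `t_death`
#'   is `NA` for cells that outlive the horizon.
#' @export
simulate_death_cohort <- function(n, phase_params, apoptosis,
                                  c0_scheme = "steady_state", window = NULL,
                                  horizon = 19.25, z = 0) {
  stopifnot(n >= 1, z >= 0)
  c0 <- sample_initial_positions(n, c0_scheme, window)
  d0 <- sample_phase_durations(n, phase_params)
  d1 <- sample_phase_durations(n, phase_params)
  rates <- growth_rates(d0$t_g1 + z, d0$t_s + z, d1$t_g1 + z, d1$t_s + z,
                        phase_params$f_g1)
  m <- 1 / stats::rlnorm(n, apoptosis$mu_td, apoptosis$sigma_td)
  res <- pad_death_times(c0, rates, m, apoptosis$p, apoptosis$pad,
                         apoptosis$variant)
  died <- res$t_death <= horizon
  tibble::tibble(
    c0 = c0, m = m,
    t_death = ifelse(died, res$t_death, NA_real_),
    t_division = res$t_division,
    divided_before_death = res$t_division < res$t_death,
    died = died
  )
}

## Bilinear interpolation of a grid surface at scattered points; points
## outside the grid evaluate to `outside`.
bilinear_eval <- function(gx, gy, fmat, x, y, outside = 0) {
  nx <- length(gx)
  ny <- length(gy)
  ix <- findInterval(x, gx)
  iy <- findInterval(y, gy)
  ix[ix == nx & x == gx[nx]] <- nx - 1L
  iy[iy == ny & y == gy[ny]] <- ny - 1L
  ok <- ix >= 1 & ix < nx & iy >= 1 & iy < ny
  out <- rep(outside, length(x))
  if (any(ok)) {
    i <- ix[ok]
    j <- iy[ok]
    wx <- (x[ok] - gx[i]) / (gx[i + 1] - gx[i])
    wy <- (y[ok] - gy[j]) / (gy[j + 1] - gy[j])
    out[ok] <- fmat[cbind(i, j)] * (1 - wx) * (1 - wy) +
      fmat[cbind(i + 1, j)] * wx * (1 - wy) +
      fmat[cbind(i, j + 1)] * (1 - wx) * wy +
      fmat[cbind(i + 1, j + 1)] * wx * wy
  }
  out
}

## Binned bivariate Gaussian KDE (FFT) evaluated at scattered points. The
## grid spans the cohort support (plus three bandwidths); points beyond it
## have essentially zero model density and evaluate to 0, which the caller
## floors.
kde2d_at_points <- function(xc, yc, xe, ye, gridsize = 160) {
  bw <- c(stats::bw.nrd0(xc), stats::bw.nrd0(yc))
  rx <- range(xc) + c(-3, 3) * bw[1]
  ry <- range(yc) + c(-3, 3) * bw[2]
  est <- KernSmooth::bkde2D(cbind(xc, yc), bandwidth = bw,
                            gridsize = c(gridsize, gridsize),
                            range.x = list(rx, ry))
  bilinear_eval(est$x1, est$x2, est$fhat, xe, ye)
}

#' KDE negative log-likelihood of (position, death-time) tuples
#'
#' Approximates the bivariate model density of initial cycle position and
#' death time from a simulated cohort with a binned Gaussian kernel density
#' estimator (Silverman bandwidth per dimension), evaluates the density at
#' each observed tuple, floors it at `density_floor` and returns the summed
#' negative log-likelihood.
#'
#' @param p,pad PAD-model parameters (used only for labeling; the cohort
#'   must already be simulated under them). May be `NULL`.
#' @param tuples A data frame with columns `c0` and `t_death` (observed).
#' @param cohort A data frame with columns `c0` and `t_death` (model draws,
#'   at least 1000 rows).
#' @param gridsize KDE grid resolution per axis.
#' @param density_floor Lower floor applied to evaluated densities
#'   (default `1e-9`).
#' @return Scalar negative log-likelihood.
#' @export
negll_pad <- function(tuples, cohort, p = NULL, pad = NULL,
                      gridsize = 160, density_floor = 1e-9) {
  stopifnot(nrow(cohort) >= 1000, nrow(tuples) >= 1)
  if (stats::sd(cohort$t_death) < 1e-12 || stats::sd(cohort$c0) < 1e-12) {
    stop("degenerate cohort: no spread in c0 or t_death", call. = FALSE)
  }
  d <- kde2d_at_points(cohort$c0, cohort$t_death, tuples$c0, tuples$t_death,
                       gridsize = gridsize)
  -sum(log(pmax(d, density_floor)))
}

#' Grid estimation of the PAD-model parameters
#'
#' Scans a `(p, pad)` grid: for each of `n_reps` independent virtual cohorts
#' (shared position/rate/slope draws within a repetition, death times
#' recomputed per grid point), computes the KDE negative log-likelihood of
#' the observed tuples and averages surfaces across repetitions. The best
#' point is the surface argmin; joint confidence regions use the chi-square
#' likelihood-ratio threshold with 2 degrees of freedom, per-parameter
#' intervals use profile likelihood with 1 degree of freedom.
#'
#' @param tuples Data frame with columns `c0` (estimated or true initial
#'   position) and `t_death` (hours); one row per dying cell.
#' @param phase_params A [phase_params()] object.
#' @param p_grid,pad_grid Numeric grids for the deceleration `p` (1/hours)
#'   and the deceleration point `pad`.
#' @param n_reps Independent sampling repetitions (default 6).
#' @param cohort_size Cells per cohort (default 8e4).
#' @param mu_td,sigma_td Lognormal parameters behind the slope draws.
#' @param c0_scheme Cohort position sampling scheme (default steady state).
#' @param variant PAD variant, see [apoptosis_params()].
#' @param horizon Observation horizon (hours).
#' @param gridsize KDE grid resolution.
#' @return A `pad_estimate` object with the averaged surface, per-repetition
#'   surfaces, `p_hat`, `pad_hat`, profile confidence intervals and a
#'   boundary flag. See [tidy.pad_estimate()], [autoplot.pad_estimate()].
#' @export
estimate_pad <- function(tuples, phase_params,
                         p_grid = seq(0, 0.4, by = 0.04),
                         pad_grid = seq(0.32, 0.92, by = 0.04),
                         n_reps = 6, cohort_size = 8e4,
                         mu_td = 1, sigma_td = 0.39,
                         c0_scheme = "steady_state",
                         variant = c("release_at_division",
                                     "extended_second_generation"),
                         horizon = 19.25, gridsize = 160) {
  variant <- match.arg(variant)
  stopifnot(length(p_grid) >= 2, length(pad_grid) >= 2, n_reps >= 1)
  np <- length(p_grid)
  nq <- length(pad_grid)
  surfaces <- array(NA_real_, dim = c(n_reps, np, nq))
  for (r in seq_len(n_reps)) {
    c0 <- sample_initial_positions(cohort_size, c0_scheme)
    d0 <- sample_phase_durations(cohort_size, phase_params)
    d1 <- sample_phase_durations(cohort_size, phase_params)
    rates <- growth_rates(d0$t_g1, d0$t_s, d1$t_g1, d1$t_s,
                          phase_params$f_g1)
    m <- 1 / stats::rlnorm(cohort_size, mu_td, sigma_td)
    for (i in seq_len(np)) {
      for (j in seq_len(nq)) {
        td <- pad_death_times(c0, rates, m, p_grid[i], pad_grid[j],
                              variant)$t_death
        keep <- td <= horizon
        surfaces[r, i, j] <- negll_pad(
          tuples,
          tibble::tibble(c0 = c0[keep], t_death = td[keep]),
          gridsize = gridsize
        )
      }
    }
  }
  surface <- apply(surfaces, c(2, 3), mean)
  idx <- which(surface == min(surface), arr.ind = TRUE)[1, ]
  on_boundary <- idx[1] %in% c(1L, np) || idx[2] %in% c(1L, nq)
  # profile intervals from a bilinearly refined surface, so CIs narrower
  # than the grid step are still resolved
  fine <- refine_surface(p_grid, pad_grid, surface)
  prof_p <- apply(fine$surface, 1, min)
  prof_pad <- apply(fine$surface, 2, min)
  thr1 <- stats::qchisq(0.95, df = 1) / 2
  ci_p <- range(fine$p[prof_p - min(prof_p) <= thr1])
  ci_pad <- range(fine$pad[prof_pad - min(prof_pad) <= thr1])
  structure(
    list(p_grid = p_grid, pad_grid = pad_grid,
         surface = surface, rep_surfaces = surfaces,
         p_hat = unname(p_grid[idx[1]]), pad_hat = unname(pad_grid[idx[2]]),
         ci_p = ci_p, ci_pad = ci_pad,
         n_reps = n_reps, cohort_size = cohort_size,
         n_tuples = nrow(tuples), variant = variant,
         horizon = horizon, on_boundary = on_boundary),
    class = "pad_estimate"
  )
}

#' @export
print.pad_estimate <- function(x, ...) {
  cat("PAD-model grid estimate\n")
  cat(sprintf("  p_hat   = %.3f 1/h  (95%% profile CI %.3f-%.3f)\n",
              x$p_hat, x$ci_p[1], x$ci_p[2]))
  cat(sprintf("  pad_hat = %.3f     (95%% profile CI %.3f-%.3f)\n",
              x$pad_hat, x$ci_pad[1], x$ci_pad[2]))
  cat(sprintf("  %d tuples, %d reps of %g cells, variant %s\n",
              x$n_tuples, x$n_reps, x$cohort_size, x$variant))
  if (x$on_boundary) cat("  WARNING: argmin on grid boundary\n")
  invisible(x)
}

#' Joint chi-square confidence region membership
#'
#' Tests whether a `(p, pad)` point lies inside the joint likelihood-ratio
#' confidence region of a [estimate_pad()] fit, by bilinear interpolation of
#' the averaged surface.
#'
#' @param x A `pad_estimate`.
#' @param p,pad Point to test.
#' @param level Confidence level (default 0.95).
#' @param rep Optional repetition index: use that repetition's surface
#'   instead of the average.
#' @return Logical.
#' @export
pad_region_contains <- function(x, p, pad, level = 0.95, rep = NULL) {
  surf <- if (is.null(rep)) x$surface else x$rep_surfaces[rep, , ]
  thr <- stats::qchisq(level, df = 2) / 2
  val <- bilinear_eval(x$p_grid, x$pad_grid, surf, p, pad, outside = Inf)
  val - min(surf) <= thr
}

## Bilinear refinement of a grid surface (refine = subdivisions per cell).
refine_surface <- function(p_grid, pad_grid, surface, refine = 8L) {
  pf <- seq(min(p_grid), max(p_grid),
            length.out = (length(p_grid) - 1L) * refine + 1L)
  qf <- seq(min(pad_grid), max(pad_grid),
            length.out = (length(pad_grid) - 1L) * refine + 1L)
  grid <- expand.grid(p = pf, pad = qf)
  vals <- bilinear_eval(p_grid, pad_grid, surface, grid$p, grid$pad,
                        outside = Inf)
  list(p = pf, pad = qf,
       surface = matrix(vals, nrow = length(pf), ncol = length(qf)))
}

## Logical region matrix at a confidence level (optionally per repetition),
## computed on the refined surface so regions narrower than the grid step
## keep their shape.
pad_region_matrix <- function(x, level = 0.95, rep = NULL, refine = 8L) {
  surf <- if (is.null(rep)) x$surface else x$rep_surfaces[rep, , ]
  fine <- refine_surface(x$p_grid, x$pad_grid, surf, refine)
  fine$surface - min(fine$surface) <= stats::qchisq(level, df = 2) / 2
}

#' Pairwise overlap of per-repetition confidence regions
#'
#' Jaccard index of the joint confidence-region grid cells between every
#' pair of sampling repetitions, a stability diagnostic for the grid
#' estimate.
#'
#' @inheritParams pad_region_contains
#' @return A tibble with `rep_a`, `rep_b`, `jaccard`.
#' @export
pad_region_overlap <- function(x, level = 0.95) {
  regs <- lapply(seq_len(x$n_reps), function(r) pad_region_matrix(x, level, r))
  pairs <- utils::combn(x$n_reps, 2)
  tibble::tibble(
    rep_a = pairs[1, ], rep_b = pairs[2, ],
    jaccard = apply(pairs, 2, function(pr) {
      a <- regs[[pr[1]]]
      b <- regs[[pr[2]]]
      sum(a & b) / sum(a | b)
    })
  )
}

#' Death-time statistics for synchronization windows
#'
#' Samples cells uniformly inside each cycle-coordinate window, simulates
#' PAD-model death times and summarizes death timing and division behaviour
#' per window - the in-silico analogue of synchronizing a population at a
#' given cycle position before TRAIL exposure.
#'
#' @param windows A list of length-2 numeric vectors `c(a, b)` inside
#'   `[0, 1]`, or a 2-column matrix/data frame.
#' @param phase_params A [phase_params()] object.
#' @param apoptosis A [apoptosis_params()] object.
#' @param n_per_window Cells per window.
#' @param horizon Observation horizon (hours).
#' @param z Phase prolongation (hours) applied to the synchronized
#'   population's cycle kinematics; the sweep emulates TRAIL-treated
#'   populations, so the default is the fitted prolongation of 3.6 h.
#' @return A tibble with one row per window: `c0_lo`, `c0_hi`, `n`,
#'   `n_died`, `median_t_death`, `iqr_t_death`, `frac_divided_before_death`,
#'   `frac_surviving_horizon`.
#' @export
synchronization_sweep <- function(windows, phase_params, apoptosis,
                                  n_per_window = 4000, horizon = 19.25,
                                  z = 3.6) {
  if (is.matrix(windows) || is.data.frame(windows)) {
    windows <- lapply(seq_len(nrow(windows)),
                      function(i) as.numeric(windows[i, 1:2]))
  }
  stopifnot(length(windows) >= 1)
  purrr::map_dfr(windows, function(w) {
    stopifnot(length(w) == 2, w[1] >= 0, w[2] <= 1, w[1] < w[2])
    coh <- simulate_death_cohort(n_per_window, phase_params, apoptosis,
                                 c0_scheme = "window", window = w,
                                 horizon = horizon, z = z)
    died <- dplyr::filter(coh, .data$died)
    tibble::tibble(
      c0_lo = w[1], c0_hi = w[2], n = nrow(coh), n_died = nrow(died),
      median_t_death = stats::median(died$t_death),
      iqr_t_death = stats::IQR(died$t_death),
      frac_divided_before_death = mean(died$divided_before_death),
      frac_surviving_horizon = 1 - nrow(died) / nrow(coh)
    )
  })
}

#' Mean apoptosis-progression trajectory
#'
#' Deterministic piecewise-linear trajectory of the apoptosis-progression
#' level `A(t)` for a cell starting at `c0`, using population-mean rates and
#' slope. Breakpoints (phase boundaries, deceleration point, division,
#' death) are listed explicitly.
#'
#' @param c0 Initial cycle position in `[0, 1)`.
#' @param rates A [growth_rates()] object with scalar mean rates.
#' @param m Mean apoptosis slope (1/hours).
#' @param p Deceleration (1/hours).
#' @param pad Deceleration point.
#' @param variant PAD variant.
#' @return A tibble with columns `t`, `c`, `a`, ending at the death time.
#' @export
mean_progression_curve <- function(c0, rates, m, p, pad,
                                   variant = c("release_at_division",
                                               "extended_second_generation")) {
  variant <- match.arg(variant)
  stopifnot(length(c0) == 1, c0 >= 0, c0 < 1, m > 0)
  f <- rates$f_g1
  ext <- variant == "extended_second_generation"
  thr <- sort(unique(c(f, pad, 1, 1 + f, if (ext) 1 + pad, 2)))
  thr <- thr[thr > c0 & thr <= 2]
  bnd <- c(0, f, 1, 1 + f, 2)
  g_of <- function(c) {
    k <- findInterval(c, bnd, rightmost.closed = FALSE)
    c(rates$g_g1, rates$g_s, rates$g_g1_f1, rates$g_s_f1)[min(k, 4)]
  }
  out <- tibble::tibble(t = 0, c = c0, a = 0)
  t_cur <- 0
  c_cur <- c0
  a_cur <- 0
  targets <- c(thr, Inf)
  for (ct in targets) {
    decel <- (c_cur >= pad && c_cur < 1) || (ext && c_cur >= 1 + pad && c_cur < 2)
    s <- m - (if (decel) p else 0)
    g <- g_of(c_cur)
    dur <- if (is.finite(ct)) (ct - c_cur) / g else Inf
    t_hit <- if (s > 0) (1 - a_cur) / s else Inf
    if (t_hit <= dur) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        t = t_cur + t_hit, c = c_cur + g * t_hit, a = 1))
      return(out)
    }
    a_cur <- max(0, a_cur + s * dur)
    t_cur <- t_cur + dur
    c_cur <- ct
    out <- dplyr::bind_rows(out, tibble::tibble(t = t_cur, c = c_cur, a = a_cur))
  }
  out
}
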