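phase_interval <- function(phase, f_g1) {
  if (phase == "G1") c(0, f_g1) else c(f_g1, 1)
}

## Monte-Carlo mean of d / p_u over m draws of phase lengths p_u, either
## truncated below at d or unconditioned; vectorized over cells via a
## (n x m) draw matrix, chunked to bound memory.
resampled_fraction <- function(d, meanlog, sdlog, m, truncated = TRUE,
                               chunk = 2e6) {
  n <- length(d)
  out <- numeric(n)
  rows_per_chunk <- max(1L, floor(chunk / m))
  for (start in seq(1L, n, by = rows_per_chunk)) {
    idx <- start:min(start + rows_per_chunk - 1L, n)
    k <- length(idx)
    if (truncated) {
      flo <- stats::plnorm(d[idx], meanlog, sdlog)
      if (any(flo > 1 - 1e-12)) {
        stop("truncation point beyond the numerical support of the ",
             "phase-length distribution", call. = FALSE)
      }
      u <- flo + stats::runif(k * m) * (1 - flo)
    } else {
      u <- stats::runif(k * m)
    }
    pu <- stats::qlnorm(u, meanlog, sdlog)
    out[idx] <- rowMeans(matrix(d[idx] / pu, nrow = k))
  }
  out
}

#' Position estimate for cells dying within their treated phase
#'
#' For a cell that died before completing the phase, the only cycle
#' information is the time `d` it had already spent in the phase. The
#' within-phase fraction is estimated as the Monte-Carlo mean of `d / p_u`
#' over draws `p_u` from the control phase-length lognormal truncated below
#' at `d` (the cell's phase demonstrably lasted longer than `d`), then
#' mapped to the absolute cycle coordinate.
#'
#' @param d Times in phase at treatment (hours, `>= 0`).
#' @param phase `"G1"` or `"SG2M"`.
#' @param phase_params A [phase_params()] object.
#' @param m_resamples Monte-Carlo draws per cell (default 1000).
#' @param truncated Use the truncated distribution (default); `FALSE`
#'   normalizes by unconditioned control draws instead.
#' @return Numeric vector of estimated positions within the phase interval.
#' @export
estimate_c0_dying <- function(d, phase = c("G1", "SG2M"), phase_params,
                              m_resamples = 1000, truncated = TRUE) {
  phase <- match.arg(phase)
  stopifnot(all(d >= 0), m_resamples >= 1)
  iv <- phase_interval(phase, phase_params$f_g1)
  width <- iv[2] - iv[1]
  if (phase == "G1") {
    meanlog <- phase_params$mu_g1
    sdlog <- phase_params$sigma_g1
  } else {
    meanlog <- phase_params$mu_s
    sdlog <- phase_params$sigma_s
  }
  frac <- resampled_fraction(d, meanlog, sdlog, m_resamples, truncated)
  frac <- pmin(pmax(frac, 0), 1 - 1e-9)
  iv[1] + width * frac
}

#' Position estimate for cells that completed their treated phase
#'
#' For a cell with an observed (TRAIL-prolonged) phase length `p`, the
#' native length is recovered by inverting the prolongation map at the
#' estimated `z`, and the position at treatment is the elapsed fraction
#' `d / T` of the phase, mapped to the absolute coordinate.
#'
#' @param p Observed total phase lengths (hours, `p > d`).
#' @param d Times in phase at treatment (hours).
#' @param z_hat Estimated prolongation (hours).
#' @inheritParams estimate_c0_dying
#' @param mode Prolongation mode, see [invert_phase_length()].
#' @return Numeric vector of estimated positions within the phase interval.
#' @export
estimate_c0_survivor <- function(p, d, z_hat, phase = c("G1", "SG2M"),
                                 phase_params,
                                 mode = c("post_exposure", "whole_phase")) {
  phase <- match.arg(phase)
  mode <- match.arg(mode)
  iv <- phase_interval(phase, phase_params$f_g1)
  width <- iv[2] - iv[1]
  t_native <- invert_phase_length(p, d, z_hat, mode)
  frac <- pmin(pmax(d / as.numeric(t_native), 0), 1 - 1e-9)
  iv[1] + width * frac
}

#' Estimate initial cycle positions for a track table
#'
#' Adds a `c0_hat` column. Strategy `"hybrid_I"` dispatches cells that died
#' inside their treated phase to truncated resampling
#' ([estimate_c0_dying()]) and phase completers to the prolongation
#' inversion ([estimate_c0_survivor()]); `"truncated_II"` uses truncated
#' resampling for every cell; `"untruncated_III"` normalizes every cell by
#' unconditioned control draws. Cells censored by the movie end without
#' completing the phase or dying get `NA` (no estimator branch applies).
#'
#' @param tracks A track tibble.
#' @param z_hat Estimated prolongation (hours), used by the survivor branch.
#' @param strategy One of `"hybrid_I"`, `"truncated_II"`,
#'   `"untruncated_III"`.
#' @param phase_params A [phase_params()] object.
#' @param m_resamples Monte-Carlo draws per resampled cell.
#' @param mode Prolongation mode.
#' @return `tracks` with an added `c0_hat` column.
#' @export
estimate_positions <- function(tracks, z_hat,
                               strategy = c("hybrid_I", "truncated_II",
                                            "untruncated_III"),
                               phase_params = nci_h460_phase_params(),
                               m_resamples = 1000,
                               mode = c("post_exposure", "whole_phase")) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  needed <- c("phase_at_trail", "d_h", "phase_end_h", "phase_end_censored",
              "death_h", "fate")
  missing_cols <- setdiff(needed, names(tracks))
  if (length(missing_cols) > 0) {
    stop("track table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  completed <- !tracks$phase_end_censored & !is.na(tracks$phase_end_h)
  died_in_phase <- !completed & !is.na(tracks$death_h)
  usable <- completed | died_in_phase
  c0_hat <- rep(NA_real_, nrow(tracks))
  for (ph in c("G1", "SG2M")) {
    sel <- tracks$phase_at_trail == ph & usable
    if (!any(sel)) next
    d <- tracks$d_h[sel]
    if (strategy == "untruncated_III") {
      c0_hat[sel] <- estimate_c0_dying(d, ph, phase_params, m_resamples,
                                       truncated = FALSE)
    } else if (strategy == "truncated_II") {
      c0_hat[sel] <- estimate_c0_dying(d, ph, phase_params, m_resamples,
                                       truncated = TRUE)
    } else {
      est <- rep(NA_real_, sum(sel))
      comp <- completed[sel]
      if (any(comp)) {
        # frame snapping can record a phase end in the treatment frame
        # (p = d); such cells sit at the phase end, so nudge p above d
        p_obs <- pmax(d[comp] + tracks$phase_end_h[sel][comp],
                      d[comp] + 1e-6)
        est[comp] <- estimate_c0_survivor(p_obs, d[comp], z_hat, ph,
                                          phase_params, mode)
      }
      if (any(!comp)) {
        est[!comp] <- estimate_c0_dying(d[!comp], ph, phase_params,
                                        m_resamples, truncated = TRUE)
      }
      c0_hat[sel] <- est
    }
  }
  dplyr::mutate(tracks, c0_hat = c0_hat)
}

#' Rank-sum test of cell fate against estimated cycle position
#'
#' Within each treated phase, compares the estimated initial positions of
#' apoptotic versus surviving cells with the two-sided rank-sum test and
#' reports group medians - the fate-association analysis run after position
#' estimation.
#'
#' @param tracks A track tibble with a `c0_hat` column (see
#'   [estimate_positions()]).
#' @return A tibble with one row per phase: group sizes, medians and the
#'   rank-sum `p.value`.
#' @export
fate_vs_position_test <- function(tracks) {
  stopifnot("c0_hat" %in% names(tracks))
  purrr::map_dfr(c("G1", "SG2M"), function(ph) {
    sub <- dplyr::filter(tracks, .data$phase_at_trail == ph,
                         !is.na(.data$c0_hat))
    a <- sub$c0_hat[sub$fate == "apoptotic"]
    s <- sub$c0_hat[sub$fate == "survivor"]
    if (length(a) < 2 || length(s) < 2) {
      return(tibble::tibble(phase_at_trail = ph,
                            n_apoptotic = length(a), n_survivor = length(s),
                            median_apoptotic = NA_real_,
                            median_survivor = NA_real_, p.value = NA_real_))
    }
    rs <- rank_sum_test(a, s)
    tibble::tibble(phase_at_trail = ph,
                   n_apoptotic = length(a), n_survivor = length(s),
                   median_apoptotic = rs$median_a,
                   median_survivor = rs$median_b,
                   p.value = rs$p.value)
  })
}

#' Sum of squared position-estimation errors by strategy
#'
#' Utility for validating estimator variants on virtual populations with
#' known true positions: runs [estimate_positions()] under each strategy
#' and accumulates the squared error of `c0_hat` against `c0_true` over the
#' usable cells.
#'
#' @inheritParams estimate_positions
#' @param strategies Strategies to compare.
#' @return A tibble with `strategy`, `n` and `sse`.
#' @export
position_sse <- function(tracks, z_hat,
                         strategies = c("hybrid_I", "truncated_II",
                                        "untruncated_III"),
                         phase_params = nci_h460_phase_params(),
                         m_resamples = 1000,
                         mode = c("post_exposure", "whole_phase")) {
  stopifnot("c0_true" %in% names(tracks))
  mode <- match.arg(mode)
  purrr::map_dfr(strategies, function(st) {
    est <- estimate_positions(tracks, z_hat, st, phase_params, m_resamples,
                              mode)
    ok <- !is.na(est$c0_hat)
    tibble::tibble(strategy = st, n = sum(ok),
                   sse = sum((est$c0_hat[ok] - est$c0_true[ok])^2))
  })
}
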