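#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the z-estimation grid
#'
#' @param x A `z_estimate` from [estimate_z()].
#' @param ... Unused.
#' @return The grid tibble (`z`, `negll_mean`, `negll_sd`) with the smoothed
#'   polynomial value in `negll_poly`.
#' @method tidy z_estimate
#' @export
tidy.z_estimate <- function(x, ...) {
  dplyr::mutate(x$grid,
                negll_poly = as.numeric(stats::predict(x$poly_fit,
                                                       newdata = x$grid)))
}

#' One-row summary of a z estimate
#'
#' @inheritParams tidy.z_estimate
#' @return A tibble with `z_hat`, `ci_low`, `ci_high`, `n_pairs`, `n_reps`,
#'   `cohort_size`, `on_boundary`.
#' @method glance z_estimate
#' @export
glance.z_estimate <- function(x, ...) {
  tibble::tibble(z_hat = x$z_hat, ci_low = x$ci[1], ci_high = x$ci[2],
                 n_pairs = x$n_pairs, n_reps = x$n_reps,
                 cohort_size = x$cohort_size, on_boundary = x$on_boundary)
}

#' Plot the negative log-likelihood profile of a z estimate
#'
#' Grid means with standard-deviation error bars, the degree-5 polynomial
#' smooth, the estimate and its 95% confidence bounds.
#'
#' @param object A `z_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot z_estimate
#' @export
autoplot.z_estimate <- function(object, ...) {
  grid <- object$grid
  zfine <- seq(min(grid$z), max(grid$z), length.out = 400)
  smooth <- tibble::tibble(
    z = zfine,
    negll = as.numeric(stats::predict(object$poly_fit,
                                      newdata = data.frame(z = zfine))))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$z, y = .data$negll_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$negll_mean - .data$negll_sd,
                                        ymax = .data$negll_mean + .data$negll_sd),
                           width = 0, color = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = smooth, ggplot2::aes(y = .data$negll),
                       color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$z_hat, color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "phase prolongation z (h)",
                  y = "negative log-likelihood",
                  title = sprintf("%s: z_hat = %.2f h [%.2f, %.2f]",
                                  object$phase, object$z_hat,
                                  object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}

#' Tidy a PAD-model surface
#'
#' @param x A `pad_estimate` from [estimate_pad()].
#' @param ... Unused.
#' @return A tibble with `p`, `pad`, `negll` and `delta_negll` (distance to
#'   the surface minimum).
#' @method tidy pad_estimate
#' @export
tidy.pad_estimate <- function(x, ...) {
  tidyr::expand_grid(p = x$p_grid, pad = x$pad_grid) |>
    dplyr::mutate(negll = purrr::map2_dbl(
      match(.data$p, x$p_grid), match(.data$pad, x$pad_grid),
      function(i, j) x$surface[i, j]),
      delta_negll = .data$negll - min(.data$negll))
}

#' One-row summary of a PAD estimate
#'
#' @inheritParams tidy.pad_estimate
#' @return A tibble with the best point, profile CIs and fitting sizes.
#' @method glance pad_estimate
#' @export
glance.pad_estimate <- function(x, ...) {
  tibble::tibble(p_hat = x$p_hat, pad_hat = x$pad_hat,
                 ci_p_low = x$ci_p[1], ci_p_high = x$ci_p[2],
                 ci_pad_low = x$ci_pad[1], ci_pad_high = x$ci_pad[2],
                 n_tuples = x$n_tuples, n_reps = x$n_reps,
                 cohort_size = x$cohort_size, variant = x$variant,
                 on_boundary = x$on_boundary)
}

#' Plot a PAD-model likelihood surface
#'
#' Raster of the averaged negative log-likelihood with the 95% joint
#' confidence contour and the best point.
#'
#' @param object A `pad_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pad_estimate
#' @export
autoplot.pad_estimate <- function(object, ...) {
  surf <- tidy.pad_estimate(object)
  thr <- stats::qchisq(0.95, 2) / 2
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$pad, y = .data$p)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$delta_negll)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$delta_negll),
                          breaks = thr, color = "white") +
    ggplot2::annotate("point", x = object$pad_hat, y = object$p_hat,
                      color = "firebrick", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "delta negLL", trans = "sqrt") +
    ggplot2::labs(x = "point of apoptosis deceleration (cycle fraction)",
                  y = "deceleration p (1/h)",
                  title = sprintf("p_hat = %.2f /h, PAD_hat = %.2f",
                                  object$p_hat, object$pad_hat)) +
    ggplot2::theme_minimal()
}

#' Plot a synchronization sweep
#'
#' Median death time with IQR ribbon per synchronization window.
#'
#' @param sweep Output of [synchronization_sweep()].
#' @return A ggplot object.
#' @export
plot_synchronization_sweep <- function(sweep) {
  sweep <- dplyr::mutate(sweep, mid = (.data$c0_lo + .data$c0_hi) / 2)
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$mid, y = .data$median_t_death)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$median_t_death - .data$iqr_t_death / 2,
      ymax = .data$median_t_death + .data$iqr_t_death / 2),
      fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "synchronization window midpoint (cycle fraction)",
                  y = "median time to death (h)") +
    ggplot2::theme_minimal()
}
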