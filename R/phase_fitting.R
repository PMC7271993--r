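## Map user-facing family names to the stats distribution roots used by
## fitdistrplus.
family_dist <- function(family) {
  switch(family,
         lognormal = "lnorm", gamma = "gamma",
         weibull = "weibull", normal = "norm",
         stop("unknown family: ", family, call. = FALSE))
}

#' Fit a duration distribution to right-censored phase lengths
#'
#' Maximum-likelihood fit of a candidate duration family where values
#' flagged as censored contribute `log(1 - CDF(value))` (the phase outlasted
#' the observation) and uncensored values contribute `log pdf(value)`.
#' Censored fitting reduces exactly to ordinary MLE when nothing is
#' censored.
#'
#' @param values Positive durations in hours.
#' @param censored Logical vector (recycled): `TRUE` marks a right-censored
#'   value (only a lower bound on the duration is known).
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`, `"normal"`.
#' @param n_params Parameter count used in the BIC penalty; defaults to the
#'   number of fitted parameters (override to reproduce alternative counting
#'   conventions).
#' @return A `censored_fit` object with `estimate`, `sd`, `loglik`, `bic`,
#'   `n`, `n_params`, `converged`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_censored <- function(values, censored = FALSE,
                         family = c("lognormal", "gamma", "weibull", "normal"),
                         n_params = NULL) {
  family <- match.arg(family)
  censored <- rep_len(censored, length(values))
  stopifnot(all(values > 0), sum(!censored) >= 2)
  if (stats::sd(values[!censored]) < 1e-12) {
    stop("degenerate sample: uncensored values are identical", call. = FALSE)
  }
  cens_df <- data.frame(left = values,
                        right = ifelse(censored, NA_real_, values))
  fit <- tryCatch(
    fitdistrplus::fitdistcens(cens_df, family_dist(family)),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && all(is.finite(fit$estimate))
  if (!converged) {
    return(structure(
      list(family = family, estimate = NULL, sd = NULL,
           loglik = NA_real_, bic = NA_real_, n = length(values),
           n_params = n_params %||% 2L, converged = FALSE),
      class = "censored_fit"))
  }
  k <- n_params %||% length(fit$estimate)
  structure(
    list(family = family,
         estimate = fit$estimate, sd = fit$sd,
         loglik = fit$loglik,
         bic = k * log(length(values)) - 2 * fit$loglik,
         n = length(values), n_params = k, converged = TRUE),
    class = "censored_fit"
  )
}

#' @export
print.censored_fit <- function(x, ...) {
  cat(sprintf("Censored %s fit (n = %d, loglik = %.2f, BIC = %.2f)\n",
              x$family, x$n, x$loglik, x$bic))
  if (x$converged) print(round(x$estimate, 4)) else cat("  NOT converged\n")
  invisible(x)
}

#' @method tidy censored_fit
#' @export
tidy.censored_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          std.error = numeric(0)))
  }
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$sd))
}

#' @method glance censored_fit
#' @export
glance.censored_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik, BIC = x$bic,
                 nobs = x$n, n_params = x$n_params, converged = x$converged)
}

#' Rank candidate duration families by BIC
#'
#' Fits each family to the same (possibly censored) sample and ranks by
#' `BIC = k log(n) - 2 logLik`, reporting the difference to the best family
#' (a difference above 2 is conventionally positive evidence).
#'
#' @inheritParams fit_censored
#' @param families Character vector of at least two family names.
#' @param gamma_n_params Optional override of the parameter count charged to
#'   the gamma family.
#' @return A tibble sorted by ascending BIC with `family`, `loglik`,
#'   `n_params`, `bic`, `delta_bic`, `converged`.
#' @export
bic_rank <- function(values, censored = FALSE,
                     families = c("lognormal", "gamma", "weibull", "normal"),
                     gamma_n_params = NULL) {
  stopifnot(length(families) >= 2)
  fits <- purrr::map(families, function(fam) {
    k <- if (fam == "gamma") gamma_n_params else NULL
    fit_censored(values, censored, fam, n_params = k)
  })
  out <- purrr::map_dfr(fits, glance.censored_fit) |>
    dplyr::rename(loglik = "logLik", bic = "BIC") |>
    dplyr::select("family", "loglik", "n_params", "bic", "converged") |>
    dplyr::arrange(.data$bic)
  dplyr::mutate(out, delta_bic = .data$bic - min(.data$bic, na.rm = TRUE))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length (`n >= 4`).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `estimate`, `conf.low`, `conf.high`, `p.value`, `n`.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("zero variance in input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  tibble::tibble(estimate = unname(ct$estimate),
                 conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
                 p.value = ct$p.value, n = length(x))
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided rank-sum test of equal location, the test used throughout for
#' comparing death-time and position distributions between groups.
#'
#' @param a,b Non-empty numeric samples.
#' @return A tibble with `statistic`, `p.value`, `median_a`, `median_b`, `n_a`,
#'   `n_b`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  tibble::tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
                 median_a = stats::median(a), median_b = stats::median(b),
                 n_a = length(a), n_b = length(b))
}

#' Compare two proportions by two labeled criteria
#'
#' Computes (i) the standard pooled two-proportion z-test and (ii) a
#' margin-of-error criterion that declares a difference significant when
#' `|p1 - p2|` exceeds `1.96 * sqrt(pbar (1 - pbar) / (n1 + n2))` under the
#' pooled null. The two criteria can disagree (the margin-of-error bound
#' uses the combined sample size rather than the variance of a difference),
#' which is why both are reported side by side.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @param conf_level Confidence level for the margin criterion.
#' @return A one-row tibble with `p1`, `p2`, `abs_difference`, `z_statistic`,
#'   `z_test_p`, `z_test_significant`, `margin_of_error`,
#'   `margin_significant`.
#' @export
proportion_difference <- function(k1, n1, k2, n2, conf_level = 0.95) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pbar <- (k1 + k2) / (n1 + n2)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_pooled <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- if (se_pooled > 0) (p1 - p2) / se_pooled else 0
  moe <- zq * sqrt(pbar * (1 - pbar) / (n1 + n2))
  tibble::tibble(
    p1 = p1, p2 = p2, abs_difference = abs(p1 - p2),
    z_statistic = z, z_test_p = 2 * stats::pnorm(-abs(z)),
    z_test_significant = 2 * stats::pnorm(-abs(z)) < 1 - conf_level,
    margin_of_error = moe,
    margin_significant = abs(p1 - p2) > moe
  )
}

#' Censored phase-length fits for a track table
#'
#' Extracts per-phase completed/censored phase lengths from a track table
#' (`p = d + phase_end` when the phase end was observed; `d` plus the movie
#' length as a right-censored lower bound otherwise) and ranks the candidate
#' families by censored BIC.
#'
#' @param tracks A track tibble.
#' @param families Families passed to [bic_rank()].
#' @return A tibble of per-phase rankings with a `phase_at_trail` column.
#' @export
fit_phases <- function(tracks,
                       families = c("lognormal", "gamma", "weibull", "normal")) {
  purrr::map_dfr(c("G1", "SG2M"), function(ph) {
    sub <- dplyr::filter(tracks, .data$phase_at_trail == ph)
    completed <- !sub$phase_end_censored & !is.na(sub$phase_end_h)
    surv_cens <- sub$phase_end_censored & sub$fate == "survivor"
    vals <- c(sub$d_h[completed] + sub$phase_end_h[completed],
              sub$d_h[surv_cens] + max(sub$phase_end_h, 19.25, na.rm = TRUE))
    cens <- c(rep(FALSE, sum(completed)), rep(TRUE, sum(surv_cens)))
    keep <- vals > 0
    dplyr::mutate(bic_rank(vals[keep], cens[keep], families),
                  phase_at_trail = ph, .before = 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
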