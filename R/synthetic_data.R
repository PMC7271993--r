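#' Death-model specifications for the track generator
#'
#' `death_lognormal()` draws death times directly from a lognormal (the
#' distribution-level description of death timing); `death_pad()` computes
#' death times mechanistically from the PAD model so that death timing
#' depends on the cycle position at treatment.
#'
#' @param mu_d,sigma_d Log-scale parameters of the death-time lognormal
#'   (defaults: the early-G1 fit, median 2.7 h, mean 2.9 h).
#' @return A `death_model` list.
#' @export
death_lognormal <- function(mu_d = 1, sigma_d = 0.39) {
  stopifnot(sigma_d > 0)
  structure(list(type = "direct_lognormal", mu_d = mu_d, sigma_d = sigma_d),
            class = "death_model")
}

#' @rdname death_lognormal
#' @param apoptosis An [apoptosis_params()] object.
#' @param use_prolonged_rates Whether the PAD dynamics run on the
#'   TRAIL-prolonged growth rates (default `FALSE`: death kinetics use the
#'   native rates).
#' @export
death_pad <- function(apoptosis = apoptosis_params(),
                      use_prolonged_rates = FALSE) {
  structure(list(type = "pad", apoptosis = apoptosis,
                 use_prolonged_rates = use_prolonged_rates),
            class = "death_model")
}

#' Configuration of a virtual time-lapse experiment
#'
#' Encodes the design of the tracking study the generator emulates: cells
#' observed for `pre_obs` hours before treatment (so the time `d` already
#' spent in the current phase is known), TRAIL added at t = 0, events
#' recorded for `post_obs` more hours at `frame_interval` resolution, with
#' right-censoring at the movie end.
#'
#' @param n_cells Number of tracked cells.
#' @param phase_params A [phase_params()] object (default: NCI-H460 control
#'   fit with log-duration correlation matched to a duration-scale Pearson
#'   correlation of 0.33).
#' @param z_true TRAIL-induced phase prolongation in hours (default 3.6).
#' @param death_model A [death_lognormal()] or [death_pad()] specification.
#' @param death_prob_g1,death_prob_s Probability that a cell treated in
#'   G1 / S-G2-M dies (defaults 0.76 and 0.72).
#' @param pre_obs,post_obs Observation windows in hours (defaults 19 and
#'   19.25).
#' @param frame_interval Imaging interval in hours (default 0.25).
#' @param c0_scheme Initial-position sampling scheme (default steady state).
#' @param prolongation_mode `"post_exposure"` (default) or `"whole_phase"`,
#'   see [phase_length_under_trail()].
#' @param sibling_mode `"count_once"` (default; a synchronous post-mitotic
#'   sibling death pair yields one recorded death event) or `"keep_both"`.
#' @param mixed_rate Fraction of post-division death events in which only
#'   one daughter dies (fate `"mixed"`, default 0.03).
#' @param snap_to_grid Snap observed event times to the frame grid
#'   (default `TRUE`).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_cells,
                              phase_params = nci_h460_phase_params(),
                              z_true = 3.6,
                              death_model = death_lognormal(),
                              death_prob_g1 = 0.76, death_prob_s = 0.72,
                              pre_obs = 19, post_obs = 19.25,
                              frame_interval = 0.25,
                              c0_scheme = "steady_state",
                              prolongation_mode = "post_exposure",
                              sibling_mode = c("count_once", "keep_both"),
                              mixed_rate = 0.03,
                              snap_to_grid = TRUE) {
  sibling_mode <- match.arg(sibling_mode)
  stopifnot(n_cells >= 0, z_true >= 0,
            death_prob_g1 >= 0, death_prob_g1 <= 1,
            death_prob_s >= 0, death_prob_s <= 1,
            pre_obs > 0, post_obs > 0, frame_interval > 0,
            mixed_rate >= 0, mixed_rate <= 1)
  structure(
    list(n_cells = n_cells, phase_params = phase_params, z_true = z_true,
         death_model = death_model,
         death_prob_g1 = death_prob_g1, death_prob_s = death_prob_s,
         pre_obs = pre_obs, post_obs = post_obs,
         frame_interval = frame_interval, c0_scheme = c0_scheme,
         prolongation_mode = prolongation_mode,
         sibling_mode = sibling_mode, mixed_rate = mixed_rate,
         snap_to_grid = snap_to_grid),
    class = "experiment_config"
  )
}

## NCI-H460 control-phase parameterization with rho_log chosen so the
## duration-scale Pearson correlation of the two phases is 0.33.
nci_h460_phase_params <- function() {
  phase_params(1.96, 0.27, 2.18, 0.19, f_g1 = 0.45,
               rho_log = rho_log_for_duration_corr(0.33, 0.27, 0.19))
}

track_columns <- c("cell_id", "parent_id", "phase_at_trail", "d_h",
                   "phase_end_h", "phase_end_censored", "division_h",
                   "division_censored", "death_h", "death_censored",
                   "fate", "c0_true")

empty_tracks <- function() {
  tibble::tibble(
    cell_id = character(0), parent_id = character(0),
    phase_at_trail = character(0), d_h = numeric(0),
    phase_end_h = numeric(0), phase_end_censored = logical(0),
    division_h = numeric(0), division_censored = logical(0),
    death_h = numeric(0), death_censored = logical(0),
    fate = character(0), c0_true = numeric(0)
  )
}

#' Generate a virtual single-cell track table
#'
#' Simulates the full statistical structure the downstream analyses assume:
#' initial positions from the configured scheme, correlated lognormal phase
#' durations (independently resampled for the daughter generation),
#' phase-specific death probabilities, death times from the configured death
#' model, TRAIL-prolonged phase progression post-treatment, right-censoring
#' at the movie end, sibling-death handling and optional snapping of event
#' times to the imaging frame grid. All times are hours relative to
#' treatment at 0.
#'
#' @param config An [experiment_config()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per tracked cell (columns `cell_id`,
#'   `parent_id`, `phase_at_trail`, `d_h`, `phase_end_h`,
#'   `phase_end_censored`, `division_h`, `division_censored`, `death_h`,
#'   `death_censored`, `fate`, `c0_true`).
#' @export
simulate_tracks <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_cells
  if (n == 0) return(empty_tracks())
  pp <- config$phase_params
  f <- pp$f_g1
  z <- config$z_true
  post_obs <- config$post_obs
  mode <- config$prolongation_mode

  c0 <- sample_initial_positions(n, config$c0_scheme)
  dur0 <- sample_phase_durations(n, pp)
  dur1 <- sample_phase_durations(n, pp)
  in_g1 <- c0 < f
  phase <- ifelse(in_g1, "G1", "SG2M")
  t_cur <- ifelse(in_g1, dur0$t_g1, dur0$t_s)
  d <- ifelse(in_g1, c0 / f * dur0$t_g1, (c0 - f) / (1 - f) * dur0$t_s)

  p_cur <- phase_length_under_trail(t_cur, d, z, mode)
  phase_end <- p_cur - d
  division <- phase_end + ifelse(in_g1, dur0$t_s + z, 0)

  apopt <- stats::runif(n) < ifelse(in_g1, config$death_prob_g1,
                                    config$death_prob_s)
  dm <- config$death_model
  if (dm$type == "direct_lognormal") {
    t_death <- stats::rlnorm(n, dm$mu_d, dm$sigma_d)
  } else {
    ap <- dm$apoptosis
    zz <- if (dm$use_prolonged_rates) z else 0
    rates <- growth_rates(dur0$t_g1 + zz, dur0$t_s + zz,
                          dur1$t_g1 + zz, dur1$t_s + zz, f)
    m <- 1 / stats::rlnorm(n, ap$mu_td, ap$sigma_td)
    t_death <- pad_death_times(c0, rates, m, ap$p, ap$pad, ap$variant)$t_death
  }
  t_death[!apopt] <- Inf

  died_pre_div <- t_death < division
  death_obs <- apopt & t_death <= post_obs
  mixed <- death_obs & !died_pre_div &
    stats::runif(n) < config$mixed_rate
  fate <- dplyr::case_when(
    death_obs & !mixed ~ "apoptotic",
    mixed ~ "mixed",
    apopt & !death_obs ~ "censored",
    TRUE ~ "survivor"
  )

  # observed phase end: the cell must complete the phase before dying and
  # before the movie ends
  pe_obs <- phase_end <= post_obs & (!apopt | phase_end < t_death)
  dv_obs <- division <= post_obs & (!apopt | division < t_death)

  tracks <- tibble::tibble(
    cell_id = sprintf("cell_%05d", seq_len(n)),
    parent_id = NA_character_,
    phase_at_trail = phase,
    d_h = d,
    phase_end_h = ifelse(pe_obs, phase_end, NA_real_),
    phase_end_censored = !pe_obs,
    division_h = ifelse(dv_obs, division, NA_real_),
    division_censored = !dv_obs,
    death_h = ifelse(death_obs, t_death, NA_real_),
    death_censored = !death_obs,
    fate = fate,
    c0_true = c0
  )

  if (config$sibling_mode == "keep_both") {
    dup <- tracks[fate == "apoptotic" & !died_pre_div, ]
    if (nrow(dup) > 0) {
      dup$parent_id <- dup$cell_id
      dup$cell_id <- paste0(dup$cell_id, "b")
      tracks <- dplyr::bind_rows(tracks, dup)
    }
  }

  if (config$snap_to_grid) {
    fi <- config$frame_interval
    snap <- function(x) round(x / fi) * fi
    tracks <- dplyr::mutate(tracks, dplyr::across(
      c("d_h", "phase_end_h", "division_h", "death_h"), snap))
  }
  tracks
}

#' @rdname simulate_tracks
#' @export
generate_population <- simulate_tracks

validate_tracks <- function(tracks) {
  missing_cols <- setdiff(track_columns, names(tracks))
  if (length(missing_cols) > 0) {
    stop("track table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(tracks$d_h) & tracks$d_h < 0)
  if (length(bad) > 0) {
    stop("negative time-in-phase `d_h` in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(tracks$fate == "apoptotic" & is.na(tracks$death_h))
  if (length(bad) > 0) {
    stop("apoptotic fate without death time in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(tracks$fate == "survivor" & !is.na(tracks$death_h))
  if (length(bad) > 0) {
    stop("survivor fate with a death time in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(tracks)
}

#' Read and write track tables
#'
#' CSV serialization of the track-table schema (UTF-8, `.` decimal
#' separator, empty string for missing values, times in hours relative to
#' treatment). Reading validates row-level invariants and errors with the
#' offending row numbers.
#'
#' @param tracks A track tibble as produced by [simulate_tracks()].
#' @param path File path.
#' @return `read_tracks()` returns the validated tibble; `write_tracks()`
#'   returns `tracks` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  validate_tracks(tracks)
  readr::write_csv(tracks[, track_columns], path, na = "")
  invisible(tracks)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tracks <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      cell_id = readr::col_character(),
      parent_id = readr::col_character(),
      phase_at_trail = readr::col_character(),
      d_h = readr::col_double(),
      phase_end_h = readr::col_double(),
      phase_end_censored = readr::col_logical(),
      division_h = readr::col_double(),
      division_censored = readr::col_logical(),
      death_h = readr::col_double(),
      death_censored = readr::col_logical(),
      fate = readr::col_character(),
      c0_true = readr::col_double()
    ),
    progress = FALSE
  )
  validate_tracks(tracks)
  tracks
}

#' Summarize a track table
#'
#' Counts and death-time summaries per (phase at treatment, fate) group,
#' plus the per-phase death fraction (apoptotic or mixed outcomes over all
#' cells treated in the phase).
#'
#' @param tracks A track tibble.
#' @return A tibble with `phase_at_trail`, `fate`, `n`, `median_t_death`,
#'   `iqr_t_death`, `death_fraction`.
#' @export
summarize_tracks <- function(tracks) {
  if (nrow(tracks) == 0) {
    return(tibble::tibble(phase_at_trail = character(0), fate = character(0),
                          n = integer(0), median_t_death = numeric(0),
                          iqr_t_death = numeric(0), death_fraction = numeric(0)))
  }
  frac <- tracks |>
    dplyr::group_by(.data$phase_at_trail) |>
    dplyr::summarise(
      death_fraction = mean(.data$fate %in% c("apoptotic", "mixed")),
      .groups = "drop")
  tracks |>
    dplyr::group_by(.data$phase_at_trail, .data$fate) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_t_death = stats::median(.data$death_h, na.rm = TRUE),
      iqr_t_death = stats::IQR(.data$death_h, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::left_join(frac, by = "phase_at_trail")
}
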