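#' Sulphate conversion efficiency
#'
#' Fraction of feed sulphate removed at pseudo-steady state,
#' `X = (c_feed - c_residual) / c_feed`, clipped to `[0, 1]` (a residual
#' above feed, which can happen under measurement noise, is clipped to 0
#' with a warning).
#'
#' @param c_feed Feed sulphate (mmol/L), must be positive.
#' @param c_residual Residual sulphate (mmol/L), non-negative; vectorised.
#' @return Conversion fraction(s) in `[0, 1]`.
#' @examples
#' conversion_efficiency(10.41, 3.54)  # ~0.66
#' @export
conversion_efficiency <- function(c_feed, c_residual) {
  if (!is.numeric(c_feed) || any(c_feed <= 0)) {
    abort("`c_feed` must be positive.", class = "lfcr_domain_error")
  }
  if (any(c_residual < 0)) {
    abort("`c_residual` must be non-negative.", class = "lfcr_domain_error")
  }
  x <- (c_feed - c_residual) / c_feed
  if (any(x < 0)) {
    warn("Residual sulphate above feed concentration; conversion clipped to 0.")
  }
  pmin(pmax(x, 0), 1)
}

#' Volumetric sulphate reduction rate at steady state
#'
#' In a continuously fed, well-mixed reactor at steady state the
#' volumetric sulphate reduction rate (VSRR) equals removal over residence
#' time: `X * c_feed / hrt` (mmol/L.h).
#'
#' @param X Conversion fraction.
#' @param c_feed Feed sulphate (mmol/L).
#' @param hrt Hydraulic residence time (h), positive.
#' @return VSRR (mmol/L.h); vectorised over `X`.
#' @examples
#' volumetric_rate(0.66, 10.41, 48)  # ~0.144 mmol/L.h
#' @export
volumetric_rate <- function(X, c_feed, hrt) {
  if (any(hrt <= 0)) abort("`hrt` must be positive.", class = "lfcr_domain_error")
  X * c_feed / hrt
}

#' Volumetric sulphide oxidation rate
#'
#' Estimated from the shortfall of measured dissolved sulphide against the
#' sulphide expected from sulphate reduction (1:1 molar):
#' `(expected - measured) / hrt`, floored at zero with a warning when
#' measured exceeds expected.
#'
#' @param expected_sulphide Expected sulphide (mmol/L), `X * c_feed`.
#' @param measured_sulphide Mean measured dissolved sulphide (mmol/L).
#' @param hrt Hydraulic residence time (h), positive.
#' @return VSOR (mmol/L.h), non-negative.
#' @examples
#' vsor_estimate(2.81, 1.50, 48)  # ~0.0273
#' @export
vsor_estimate <- function(expected_sulphide, measured_sulphide, hrt) {
  if (any(hrt <= 0)) abort("`hrt` must be positive.", class = "lfcr_domain_error")
  if (any(expected_sulphide < 0)) {
    abort("`expected_sulphide` must be non-negative.", class = "lfcr_domain_error")
  }
  v <- (expected_sulphide - measured_sulphide) / hrt
  if (any(v < 0)) {
    warn("Measured sulphide above expected; VSOR floored at 0.")
  }
  pmax(v, 0)
}

#' Reduce sample records to per-stage pseudo-steady-state summaries
#'
#' For each temperature stage, averages the final `n_window` sampling times
#' (the pseudo-steady-state window preceding the stage-end biofilm
#' harvest), separately for the bulk compartment (mean of ports P1-P4) and
#' the effluent, and computes conversion, VSRR, expected sulphide, VSOR and
#' volatile fatty acid rates. Utilisation rates are `(feed - residual)/hrt`;
#' for species absent from the feed the same quantity is negative and is
#' reported as a production rate (`-(feed - residual)/hrt`).
#'
#' @param records Sample-record tibble with columns `time_h`, `port`,
#'   `temp_C`, `sulphate_mmol_L`, `sulphide_mmol_L`, `lactate_mmol_L`,
#'   `acetate_mmol_L`, `propionate_mmol_L` (as produced by
#'   [simulate_reactor()] or read from CSV).
#' @param feed A [feed_spec()].
#' @param schedule A [reactor_schedule()].
#' @param n_window Number of final sampling times per stage to average.
#'
#' @return A tibble with one row per stage per compartment: `stage`,
#'   `temp_C`, `compartment`, `n_samples`, mean analyte concentrations,
#'   `conversion`, `vsrr_mmol_L_h`, `expected_sulphide_mmol_L`,
#'   `vsor_mmol_L_h`, `lactate_util_mmol_L_h`, `acetate_prod_mmol_L_h`,
#'   `propionate_prod_mmol_L_h`.
#' @examples
#' sim <- simulate_reactor(feed_spec(), kinetic_params(),
#'   reactor_schedule(stage_temps_c = 30), noise_cv = 0, seed = 1)
#' stage_summaries(sim$samples, sim$feed, sim$schedule)
#' @export
stage_summaries <- function(records, feed, schedule, n_window = 3) {
  stopifnot(inherits(feed, "feed_spec"), inherits(schedule, "reactor_schedule"))
  needed <- c("time_h", "port", "temp_C", "sulphate_mmol_L", "sulphide_mmol_L",
              "lactate_mmol_L", "acetate_mmol_L", "propionate_mmol_L")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "lfcr_schema_error")
  }
  hrt <- schedule$hrt
  feed_conc <- c(
    sulphate = feed$sulphate_mmol_l,
    sulphide = 0,
    lactate = if (feed$carbon_source == "lactate") feed$carbon_mmol_l else 0,
    acetate = if (feed$carbon_source == "acetate") feed$carbon_mmol_l else 0,
    propionate = 0
  )

  windows <- purrr::pmap_dfr(
    schedule$stages,
    function(stage, temp_c, start_h, end_h) {
      in_stage <- sort(unique(records$time_h[records$time_h > start_h &
                                               records$time_h <= end_h]))
      if (length(in_stage) == 0) {
        abort(sprintf("No samples found for stage %d (%g degC).", stage, temp_c),
          class = "lfcr_missing_stage_error")
      }
      tibble(stage = stage, temp_C = temp_c,
             time_h = utils::tail(in_stage, n_window))
    }
  )

  records |>
    dplyr::inner_join(windows, by = "time_h", suffix = c("", ".win")) |>
    dplyr::mutate(compartment = ifelse(.data$port == "effluent", "effluent", "bulk")) |>
    dplyr::group_by(.data$stage, temp_C = .data$temp_C.win, .data$compartment) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      sulphate_mmol_L = mean(.data$sulphate_mmol_L),
      sulphide_mmol_L = mean(.data$sulphide_mmol_L),
      lactate_mmol_L = mean(.data$lactate_mmol_L),
      acetate_mmol_L = mean(.data$acetate_mmol_L),
      propionate_mmol_L = mean(.data$propionate_mmol_L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      conversion = conversion_efficiency(feed_conc[["sulphate"]], .data$sulphate_mmol_L),
      vsrr_mmol_L_h = volumetric_rate(.data$conversion, feed_conc[["sulphate"]], hrt),
      expected_sulphide_mmol_L = .data$conversion * feed_conc[["sulphate"]],
      vsor_mmol_L_h = vsor_estimate(.data$expected_sulphide_mmol_L,
                                    .data$sulphide_mmol_L, hrt),
      lactate_util_mmol_L_h = (feed_conc[["lactate"]] - .data$lactate_mmol_L) / hrt,
      acetate_prod_mmol_L_h = (.data$acetate_mmol_L - feed_conc[["acetate"]]) / hrt,
      propionate_prod_mmol_L_h = (.data$propionate_mmol_L - feed_conc[["propionate"]]) / hrt
    ) |>
    dplyr::arrange(.data$stage, .data$compartment)
}
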