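#' Stage rates against temperature
#'
#' Volumetric sulphate reduction and VFA rates per stage, bulk
#' compartment.
#'
#' @param summaries A [stage_summaries()] tibble.
#' @return A ggplot object.
#' @export
plot_stage_rates <- function(summaries) {
  summaries |>
    dplyr::filter(.data$compartment == "bulk") |>
    dplyr::select("temp_C",
      VSRR = "vsrr_mmol_L_h",
      `lactate utilisation` = "lactate_util_mmol_L_h",
      `acetate production` = "acetate_prod_mmol_L_h",
      `propionate production` = "propionate_prod_mmol_L_h"
    ) |>
    tidyr::pivot_longer(-"temp_C", names_to = "rate", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(.data$temp_C, .data$value, colour = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "temperature (degC)", y = "rate (mmol/L.h)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sulphur pools per stage
#'
#' Stacked view of where converted sulphur ended up: harvested biofilm,
#' aqueous effluent and the unaccounted (gap) pool.
#'
#' @param ledgers A [stage_ledgers()] tibble.
#' @return A ggplot object.
#' @export
plot_sulphur_ledger <- function(ledgers) {
  ledgers |>
    dplyr::select("temp_C",
      `FSB-S` = "fsb_S_g",
      `aqueous S` = "aqueous_effluent_S_g",
      `gap S` = "gap_S_g"
    ) |>
    tidyr::pivot_longer(-"temp_C", names_to = "pool", values_to = "mass_g") |>
    ggplot2::ggplot(ggplot2::aes(factor(.data$temp_C), .data$mass_g, fill = .data$pool)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "stage temperature (degC)", y = "sulphur (g)", fill = NULL) +
    ggplot2::theme_minimal()
}
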