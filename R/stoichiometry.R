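#' Reaction stoichiometry table
#'
#' The three reactions the flux accounting is based on, with signed molar
#' coefficients (negative = consumed):
#' \itemize{
#'   \item fermentation: 3 lactate -> 1 acetate + 2 propionate + 1 HCO3- + 1 H+
#'   \item incomplete oxidation: 2 lactate + 1 SO4^2- -> 1 HS- + 2 acetate
#'     + 2 HCO3- + 1 H+
#'   \item complete acetate oxidation: 1 acetate + 1 SO4^2- -> 1 HS- + 2 HCO3-
#' }
#'
#' @return A tibble with columns `reaction`, `species`, `coef`.
#' @export
stoichiometry_constants <- function() {
  tibble(
    reaction = rep(c("fermentation", "incomplete_oxidation", "acetate_oxidation"),
                   times = c(5, 6, 4)),
    species = c(
      "lactate", "acetate", "propionate", "HCO3", "H",
      "lactate", "sulphate", "sulphide", "acetate", "HCO3", "H",
      "acetate", "sulphate", "sulphide", "HCO3"
    ),
    coef = c(
      -3, 1, 2, 1, 1,
      -2, -1, 1, 2, 2, 1,
      -1, -1, 1, 2
    )
  )
}

#' Partition the lactate flux between fermentation and sulphate reduction
#'
#' Propionate is treated as a pure fermentation marker (3 lactate ->
#' 1 acetate + 2 propionate), so fermented lactate is 1.5x the propionate
#' production rate. Sulphate reduction in lactate-fed mode is attributed to
#' incomplete lactate oxidation (2 lactate per sulphate), which also yields
#' 2 acetate per sulphate. Acetate produced beyond the sum of those two
#' sources is "excess" acetate, attributed to fermentation of yeast
#' extract; lactate utilisation not covered by the two pathways is reported
#' as unaccounted (negative values indicate over-attribution and are
#' flagged).
#'
#' @param r_lactate_util Lactate utilisation rate (mmol/L.h), >= 0.
#' @param r_propionate_prod Propionate production rate (mmol/L.h), >= 0.
#' @param r_sulphate_red Sulphate reduction rate (VSRR, mmol/L.h), >= 0.
#' @param r_acetate_net Net acetate production rate (mmol/L.h); may be
#'   negative (net consumption).
#' @param tol Flag tolerance (mmol/L.h) on `lactate_unaccounted`.
#'
#' @return A one-row tibble with `lactate_fermented`, `lactate_oxidised`,
#'   `lactate_unaccounted`, `acetate_from_fermentation`, `acetate_from_bsr`,
#'   `acetate_expected`, `acetate_excess` (all mmol/L.h) and a `flags`
#'   character column (`;`-separated diagnostics, `""` if none).
#' @examples
#' partition_lactate(0.228, 0.04, 0.06, 0.20)
#' @export
partition_lactate <- function(r_lactate_util, r_propionate_prod,
                              r_sulphate_red, r_acetate_net, tol = 1e-6) {
  if (any(c(r_lactate_util, r_propionate_prod, r_sulphate_red) < 0)) {
    abort("Utilisation and production rates must be non-negative.",
      class = "lfcr_domain_error")
  }
  lactate_fermented <- 1.5 * r_propionate_prod
  acetate_from_fermentation <- 0.5 * r_propionate_prod
  lactate_oxidised <- 2 * r_sulphate_red
  acetate_from_bsr <- 2 * r_sulphate_red
  acetate_expected <- acetate_from_fermentation + acetate_from_bsr
  acetate_excess <- r_acetate_net - acetate_expected
  lactate_unaccounted <- r_lactate_util - lactate_fermented - lactate_oxidised

  flags <- character(0)
  if (lactate_unaccounted < -tol) {
    flags <- c(flags, "over_attribution: fermentation + oxidation exceed lactate utilisation")
  }
  if (acetate_excess > tol) {
    flags <- c(flags, "acetate_excess: more acetate than donor stoichiometry allows (yeast extract)")
  }
  tibble(
    lactate_fermented = lactate_fermented,
    lactate_oxidised = lactate_oxidised,
    lactate_unaccounted = lactate_unaccounted,
    acetate_from_fermentation = acetate_from_fermentation,
    acetate_from_bsr = acetate_from_bsr,
    acetate_expected = acetate_expected,
    acetate_excess = acetate_excess,
    flags = paste(flags, collapse = "; ")
  )
}

#' Acetate-fed donor balance
#'
#' Under complete acetate oxidation the expected acetate utilisation
#' equals the sulphate reduction rate (1:1 molar). Reports the discrepancy
#' `r_acetate_util - r_sulphate_red`; a negative utilisation (net acetate
#' production, typically from yeast extract) is allowed and flagged.
#'
#' @param r_acetate_util Acetate utilisation rate (mmol/L.h); may be
#'   negative.
#' @param r_sulphate_red Sulphate reduction rate (mmol/L.h), >= 0.
#' @return A one-row tibble with `expected_acetate_util`, `discrepancy` and
#'   `flags`.
#' @examples
#' acetate_mode_balance(-0.02, 0.05)
#' @export
acetate_mode_balance <- function(r_acetate_util, r_sulphate_red) {
  if (any(r_sulphate_red < 0)) {
    abort("`r_sulphate_red` must be non-negative.", class = "lfcr_domain_error")
  }
  flags <- if (r_acetate_util < 0) "net_production: acetate produced, not consumed" else ""
  tibble(
    expected_acetate_util = r_sulphate_red,
    discrepancy = r_acetate_util - r_sulphate_red,
    flags = flags
  )
}

#' COD-to-sulphate ratio of a feed
#'
#' Chemical oxygen demand of the electron donor (lactate: 96 g O2/mol;
#' acetate: 64 g O2/mol) divided by the sulphate mass concentration.
#'
#' @param feed A [feed_spec()] object (or a bare list with
#'   `carbon_source`, `carbon_mmol_l`, `sulphate_g_l`).
#' @return Dimensionless COD/SO4 ratio.
#' @examples
#' cod_ratio(feed_spec(carbon_source = "acetate"))  # ~0.72
#' @export
cod_ratio <- function(feed) {
  src <- feed$carbon_source
  if (!src %in% names(COD_PER_MOL)) {
    abort(sprintf("Unknown carbon source '%s'.", src), class = "lfcr_config_error")
  }
  cod_g_l <- feed$carbon_mmol_l * COD_PER_MOL[[src]] / 1000
  cod_g_l / feed$sulphate_g_l
}

#' Partition fluxes for every stage of a summary table
#'
#' Applies [partition_lactate()] (lactate-fed) or [acetate_mode_balance()]
#' (acetate-fed) to each bulk-compartment row of a [stage_summaries()]
#' table. Noise-induced negative utilisation or production rates are
#' clamped to zero before partitioning (the clamp amount is below the
#' measurement floor at the stage level).
#'
#' @param summaries A [stage_summaries()] tibble.
#' @param feed A [feed_spec()].
#' @return A tibble with one row per stage joining the stage identifiers to
#'   the partition columns.
#' @export
partition_stages <- function(summaries, feed) {
  bulk <- dplyr::filter(summaries, .data$compartment == "bulk")
  if (feed$carbon_source == "lactate") {
    parts <- purrr::pmap_dfr(
      list(bulk$lactate_util_mmol_L_h, bulk$propionate_prod_mmol_L_h,
           bulk$vsrr_mmol_L_h, bulk$acetate_prod_mmol_L_h),
      function(lu, pp, sr, an) {
        partition_lactate(max(lu, 0), max(pp, 0), max(sr, 0), an)
      }
    )
  } else {
    parts <- purrr::pmap_dfr(
      list(-bulk$acetate_prod_mmol_L_h, bulk$vsrr_mmol_L_h),
      function(au, sr) acetate_mode_balance(au, max(sr, 0))
    )
  }
  dplyr::bind_cols(bulk[c("stage", "temp_C")], parts)
}
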