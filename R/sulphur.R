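#' Sulphur recovered in harvested biofilm
#'
#' Sum of `dry_mass * frac_S` over the harvest records falling inside an
#' interval (interval bounds `(start, end]` in hours).
#'
#' @param harvests Tibble with `time_h`, `dry_mass_g`, `frac_S`.
#' @param interval Numeric length-2 `(start_h, end_h)`; `NULL` takes all
#'   records.
#' @return Sulphur mass (g).
#' @examples
#' fsb_sulphur(tibble::tibble(time_h = 288, dry_mass_g = 10, frac_S = 0.29))
#' @export
fsb_sulphur <- function(harvests, interval = NULL) {
  if (!is.null(interval)) {
    harvests <- harvests[harvests$time_h > interval[1] & harvests$time_h <= interval[2], ]
  }
  if (nrow(harvests) == 0) return(0)
  sum(harvests$dry_mass_g * harvests$frac_S)
}

#' Sulphur converted from sulphate over an interval
#'
#' Total sulphide-sulphur generated by sulphate reduction:
#' `vsrr * volume * duration * 32.06 / 1000` grams.
#'
#' @param vsrr Volumetric sulphate reduction rate (mmol/L.h).
#' @param volume Reactor working volume (L).
#' @param duration Interval length (h).
#' @return Mass of converted sulphur (g).
#' @examples
#' converted_sulphide_s(0.144, 2, 288)  # ~2.66 g over one 12-day harvest interval
#' @export
converted_sulphide_s <- function(vsrr, volume, duration) {
  if (any(c(vsrr, volume, duration) < 0)) {
    abort("All inputs must be non-negative.", class = "lfcr_domain_error")
  }
  vsrr * volume * duration * MM[["sulphur"]] / 1000
}

#' Sulphur ledger over a harvest interval
#'
#' Accounts for the sulphur converted from sulphate across its sinks: the
#' harvested floating sulphur biofilm (FSB-S), the aqueous effluent
#' (dissolved sulphide carried out by the flow, integrated trapezoidally
#' over the effluent sample series), an optional re-oxidised-to-sulphate
#' term, an optional dissolved-inventory change, and the unaccounted "gap"
#' sulphur defined by closure. Recovery is FSB-S as a percentage of
#' converted sulphur.
#'
#' @param vsrr Volumetric sulphate reduction rate over the interval
#'   (mmol/L.h).
#' @param volume Reactor working volume (L).
#' @param interval Numeric `(start_h, end_h)`.
#' @param harvests Harvest-record tibble (see [fsb_sulphur()]).
#' @param effluent Tibble with `time_h` and `sulphide_mmol_L` for effluent
#'   samples covering the interval (endpoints included if present).
#' @param hrt Hydraulic residence time (h).
#' @param reoxidised_S Sulphur re-oxidised completely back to sulphate (g);
#'   0 by default (negligible under an intact biofilm, a scenario knob for
#'   failed-biofilm cases).
#' @param inventory_S Change in dissolved sulphide inventory over the
#'   interval (g); 0 by default, supply for exact closure against a
#'   simulated truth.
#' @return A one-row tibble: `start_h`, `end_h`, `converted_S_g`,
#'   `fsb_S_g`, `aqueous_effluent_S_g`, `reoxidised_S_g`, `gap_S_g`,
#'   `recovery_pct`, `aqueous_pct`, `reoxidised_pct`, `gap_pct`, `flags`.
#' @export
sulphur_ledger <- function(vsrr, volume, interval, harvests, effluent, hrt,
                           reoxidised_S = 0, inventory_S = 0) {
  if (hrt <= 0) abort("`hrt` must be positive.", class = "lfcr_domain_error")
  duration <- interval[2] - interval[1]
  if (duration <= 0) abort("Interval must have positive length.", class = "lfcr_domain_error")
  converted <- converted_sulphide_s(vsrr, volume, duration)
  fsb <- fsb_sulphur(harvests, interval)
  if (converted == 0 && fsb > 0) {
    abort("Recovery undefined: sulphur harvested with zero converted sulphur.",
      class = "lfcr_undefined_recovery_error")
  }

  eff <- effluent[effluent$time_h >= interval[1] & effluent$time_h <= interval[2], ]
  eff <- eff[order(eff$time_h), ]
  aqueous <- if (nrow(eff) >= 2) {
    flux <- eff$sulphide_mmol_L * (volume / hrt) * MM[["sulphur"]] / 1000  # g/h
    sum(diff(eff$time_h) * (head(flux, -1) + tail(flux, -1)) / 2)
  } else if (nrow(eff) == 1) {
    eff$sulphide_mmol_L * (volume / hrt) * MM[["sulphur"]] / 1000 * duration
  } else 0

  gap <- converted - fsb - aqueous - reoxidised_S - inventory_S
  flags <- if (gap < 0) "over_recovery: accounted sulphur exceeds converted sulphur" else ""
  pct <- function(x) if (converted > 0) 100 * x / converted else NA_real_
  tibble(
    start_h = interval[1], end_h = interval[2],
    converted_S_g = converted, fsb_S_g = fsb,
    aqueous_effluent_S_g = aqueous, reoxidised_S_g = reoxidised_S,
    inventory_S_g = inventory_S, gap_S_g = gap,
    recovery_pct = pct(fsb), aqueous_pct = pct(aqueous),
    reoxidised_pct = pct(reoxidised_S),
    gap_pct = pct(gap + inventory_S),
    flags = flags
  )
}

#' Per-stage sulphur ledgers from analysis tables
#'
#' Convenience wrapper building one [sulphur_ledger()] per temperature
#' stage from a [stage_summaries()] table, the harvest records and the
#' effluent sample series.
#'
#' @param summaries A [stage_summaries()] tibble.
#' @param harvests Harvest-record tibble.
#' @param effluent_samples Sample records for the effluent port (columns
#'   `time_h`, `sulphide_mmol_L`).
#' @param schedule A [reactor_schedule()].
#' @param volume Reactor working volume (L).
#' @return A tibble with one ledger row per stage plus `stage`, `temp_C`.
#' @export
stage_ledgers <- function(summaries, harvests, effluent_samples, schedule, volume = 2) {
  bulk <- dplyr::filter(summaries, .data$compartment == "bulk")
  purrr::pmap_dfr(
    schedule$stages,
    function(stage, temp_c, start_h, end_h) {
      row <- bulk[bulk$stage == stage, ]
      led <- sulphur_ledger(
        vsrr = row$vsrr_mmol_L_h, volume = volume,
        interval = c(start_h, end_h), harvests = harvests,
        effluent = effluent_samples, hrt = schedule$hrt
      )
      dplyr::bind_cols(tibble(stage = stage, temp_C = temp_c), led)
    }
  )
}

#' Elemental composition closure of harvested biofilm
#'
#' CHNS analysis determines the organic and sulphur fractions of the dry
#' biofilm; the remainder is the inorganic fraction (a struvite-rich
#' crystalline precipitate in this system): `inorganic = 1 - (C+H+N+S)`,
#' clipped at 0 with a warning for rounding overshoot; a sum materially
#' above 1 is an inconsistent composition and raises an error.
#'
#' @param frac_C,frac_H,frac_N,frac_S Mass fractions in `[0, 1]`.
#' @return A one-row tibble with the four fractions and `inorganic_frac`.
#' @examples
#' elemental_closure(0.11, 0.02, 0.02, 0.29)  # inorganic 0.56
#' @export
elemental_closure <- function(frac_C, frac_H, frac_N, frac_S) {
  fr <- c(frac_C, frac_H, frac_N, frac_S)
  if (any(fr < 0) || any(fr > 1)) {
    abort("Fractions must lie in [0, 1].", class = "lfcr_domain_error")
  }
  s <- sum(fr)
  if (s > 1 + 1e-6) {
    abort("CHNS fractions sum above 1: inconsistent composition.",
      class = "lfcr_composition_error")
  }
  inorg <- 1 - s
  if (inorg < 0) {
    warn("CHNS fractions sum marginally above 1; inorganic fraction clipped to 0.")
    inorg <- 0
  }
  tibble(frac_C = frac_C, frac_H = frac_H, frac_N = frac_N, frac_S = frac_S,
         inorganic_frac = inorg)
}
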