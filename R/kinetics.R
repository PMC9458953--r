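#' Kinetic parameters of the simulated reactor community
#'
#' Lumped kinetics for the sulphate-reducing and sulphide-oxidising
#' communities. Biomass is folded into the maximum rates (the observable is
#' a volumetric rate, not a cell count), and temperature dependence follows
#' a two-regime Arrhenius law: a moderate activation energy in the
#' adapted range above the critical temperature and a steeper one below it,
#' continuous at the break.
#'
#' Defaults reproduce the 2 L lactate-fed operating point: a maximum
#' volumetric sulphate reduction rate of 0.144 mmol/L.h at 30 degC
#' (303.15 K), activation energies of 19.0 kJ/mol above and 65.7 kJ/mol
#' below a critical temperature of 15 degC (288.15 K).
#'
#' @param k_max Maximum volumetric sulphate reduction rate at `T_ref`
#'   (mmol/L.h).
#' @param K_S Sulphate half-saturation constant (mmol/L).
#' @param T_ref Reference absolute temperature (K).
#' @param Ea_above,Ea_below Activation energies (J/mol) at and above,
#'   respectively below, `T_crit`. `Ea_below >= Ea_above` is expected
#'   (stress regime is steeper).
#' @param T_crit Critical temperature (K) at which the two Arrhenius
#'   regimes meet.
#' @param k_ox_max Maximum volumetric sulphide oxidation rate at full open
#'   surface (mmol/L.h).
#' @param K_HS Sulphide half-saturation of the oxidation rate (mmol/L).
#' @param biofilm_regrowth First-order surface coverage regrowth rate
#'   (1/h), scaled by sulphide availability.
#' @param eta_S0 Fraction of oxidised sulphide captured in the floating
#'   biofilm as elemental sulphur; the remainder becomes colloidal sulphur
#'   that leaves with the effluent or settles in lines ("gap" sulphur).
#' @param ferm_fraction Fraction of lactate uptake routed to fermentation
#'   (propionate-producing) rather than incomplete oxidation.
#'
#' @return A `kinetic_params` list.
#' @examples
#' kinetic_params()
#' @export
kinetic_params <- function(k_max = 0.144,
                           K_S = 0.1,
                           T_ref = 303.15,
                           Ea_above = 19000,
                           Ea_below = 65700,
                           T_crit = 288.15,
                           k_ox_max = 2,
                           K_HS = 0.5,
                           biofilm_regrowth = 0.05,
                           eta_S0 = 0.30,
                           ferm_fraction = 0.15) {
  vals <- c(
    k_max = k_max, K_S = K_S, T_ref = T_ref, Ea_above = Ea_above,
    Ea_below = Ea_below, T_crit = T_crit, k_ox_max = k_ox_max, K_HS = K_HS,
    biofilm_regrowth = biofilm_regrowth
  )
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("All rates, energies and temperatures must be finite and non-negative.",
      class = "lfcr_domain_error"
    )
  }
  if (Ea_below < Ea_above) {
    warn("`Ea_below` < `Ea_above`: the sub-critical regime is usually the steeper one.")
  }
  if (eta_S0 < 0 || eta_S0 > 1 || ferm_fraction < 0 || ferm_fraction > 1) {
    abort("`eta_S0` and `ferm_fraction` must lie in [0, 1].", class = "lfcr_domain_error")
  }
  structure(
    list(
      k_max = k_max, K_S = K_S, T_ref = T_ref,
      Ea_above = Ea_above, Ea_below = Ea_below, T_crit = T_crit,
      k_ox_max = k_ox_max, K_HS = K_HS,
      biofilm_regrowth = biofilm_regrowth,
      eta_S0 = eta_S0, ferm_fraction = ferm_fraction
    ),
    class = "kinetic_params"
  )
}

#' Two-regime Arrhenius temperature multiplier
#'
#' Dimensionless factor applied to `k_max`: 1 at the reference temperature,
#' following `exp(-Ea_above/R * (1/T - 1/T_ref))` down to the critical
#' temperature, and continuing below it from the value at `T_crit` with the
#' steeper slope `Ea_below`. The function is continuous at `T_crit`.
#'
#' @param T_K Absolute temperature (K); vectorised.
#' @param params A [kinetic_params()] object.
#' @return Numeric vector of multipliers.
#' @examples
#' p <- kinetic_params()
#' temperature_factor(303.15, p)  # 1 at reference
#' temperature_factor(288.15, p)  # warm-regime value at 15 degC
#' @export
temperature_factor <- function(T_K, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(!is.finite(T_K)) || any(T_K <= 0)) {
    abort("Absolute temperature must be positive.", class = "lfcr_domain_error")
  }
  f_warm <- exp(-params$Ea_above / R_GAS * (1 / T_K - 1 / params$T_ref))
  f_at_crit <- exp(-params$Ea_above / R_GAS * (1 / params$T_crit - 1 / params$T_ref))
  f_cold <- f_at_crit * exp(-params$Ea_below / R_GAS * (1 / T_K - 1 / params$T_crit))
  ifelse(T_K >= params$T_crit, f_warm, f_cold)
}

celsius_to_kelvin <- function(temp_c) temp_c + KELVIN0
kelvin_to_celsius <- function(temp_k) temp_k - KELVIN0
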