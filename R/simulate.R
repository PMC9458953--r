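#' Initial reactor state
#'
#' The reactor starts filled with fresh feed: sulphate and the carbon
#' source at feed concentration, no sulphide or fermentation products, a
#' bare surface and no accumulated biofilm.
#'
#' @param feed A [feed_spec()] object.
#' @return Named numeric state vector used by [reactor_step()].
#' @export
initial_state <- function(feed) {
  c(
    time = 0,
    sulphate = feed$sulphate_mmol_l,
    sulphide = 0,
    lactate = if (feed$carbon_source == "lactate") feed$carbon_mmol_l else 0,
    acetate = if (feed$carbon_source == "acetate") feed$carbon_mmol_l else 0,
    propionate = 0,
    coverage = 0,
    film_S = 0, film_mass = 0, gap_S = 0,
    cum_in_S = 0, cum_out_S = 0, cum_out_HS_S = 0,
    harvested_S = 0, harvested_mass = 0
  )
}

#' Advance the reactor state by one explicit time step
#'
#' Well-mixed single-compartment mass balance. All dissolved species are
#' diluted toward feed values at rate `1/hrt`. Sulphate is reduced at a
#' Monod rate with a two-regime Arrhenius temperature factor, gated by
#' electron-donor availability: lactate uptake is split between
#' fermentation (3 lactate -> 1 acetate + 2 propionate) and incomplete
#' oxidation (2 lactate + 1 sulphate -> 1 sulphide + 2 acetate); when
#' lactate cannot carry the full kinetic demand, accumulated acetate serves
#' as secondary donor via complete oxidation (1 acetate + 1 sulphate ->
#' 1 sulphide). Sulphide is produced 1:1 with sulphate reduced and
#' partially oxidised at the air-liquid interface at a rate proportional to
#' the open (biofilm-free) surface fraction; a fraction `eta_S0` of the
#' oxidised sulphur is captured in the floating film, the rest enters the
#' unaccounted colloidal ("gap") pool. Surface coverage regrows towards 1
#' at `biofilm_regrowth`, scaled by sulphide availability.
#'
#' @param state Named state vector, see [initial_state()].
#' @param temp_c Operating temperature (degC).
#' @param feed A [feed_spec()].
#' @param params A [kinetic_params()].
#' @param dt Time step (h); must not exceed `hrt / 100`.
#' @param hrt Hydraulic residence time (h).
#' @param volume Reactor working volume (L).
#' @param film_frac_s Mass fraction of sulphur in the dry floating biofilm,
#'   used to convert captured film sulphur into dry mass.
#'
#' @return The updated state vector.
#' @export
reactor_step <- function(state, temp_c, feed, params, dt, hrt,
                         volume = 2, film_frac_s = 0.29) {
  if (dt <= 0 || dt > hrt / 100) {
    abort("`dt` must be positive and at most hrt/100.", class = "lfcr_domain_error")
  }
  D <- 1 / hrt
  f_T <- temperature_factor(celsius_to_kelvin(temp_c), params)

  S <- state[["sulphate"]]; HS <- state[["sulphide"]]
  L <- state[["lactate"]]; A <- state[["acetate"]]; P <- state[["propionate"]]
  cov <- state[["coverage"]]

  # kinetic demand for sulphate reduction (mmol/L.h)
  r_dem <- params$k_max * f_T * S / (params$K_S + S)

  f <- params$ferm_fraction
  if (feed$carbon_source == "lactate") {
    u_dem <- if (f < 1) 2 * r_dem / (1 - f) else 0
    U <- min(u_dem, max(L, 0) / dt)            # donor availability gate
    r_Lf <- f * U                              # lactate to fermentation
    r_Lo <- (1 - f) * U                        # lactate to incomplete oxidation
    r_S_lac <- r_Lo / 2
    r_S_ace <- min(r_dem - r_S_lac, max(A, 0) / dt)
    r_S_ace <- max(r_S_ace, 0)
    A_in <- 0; L_in <- feed$carbon_mmol_l
  } else {
    U <- 0; r_Lf <- 0; r_Lo <- 0; r_S_lac <- 0
    r_S_ace <- min(r_dem, max(A, 0) / dt)
    A_in <- feed$carbon_mmol_l; L_in <- 0
  }
  r_S <- r_S_lac + r_S_ace
  if (r_S * dt > S) {                          # sulphate availability gate
    scale <- S / (r_S * dt)
    r_S_lac <- r_S_lac * scale; r_S_ace <- r_S_ace * scale
    r_Lo <- 2 * r_S_lac; r_S <- r_S_lac + r_S_ace
  }

  r_ox <- params$k_ox_max * (1 - cov) * HS / (params$K_HS + HS)
  r_ox <- min(r_ox, max(HS, 0) / dt)

  y <- feed$yeast_extract_acetate_rate

  S2 <- S + dt * (D * (feed$sulphate_mmol_l - S) - r_S)
  HS2 <- HS + dt * (r_S - r_ox - D * HS)
  L2 <- L + dt * (D * (L_in - L) - U)
  A2 <- A + dt * (D * (A_in - A) + r_Lf / 3 + r_Lo + y - r_S_ace)
  P2 <- P + dt * (D * (0 - P) + (2 / 3) * r_Lf)

  conc2 <- c(sulphate = S2, sulphide = HS2, lactate = L2, acetate = A2, propionate = P2)
  if (any(conc2 < -1e-9)) {
    bad <- names(conc2)[which.min(conc2)]
    abort(
      sprintf("Integrator step would drive %s below zero; reduce `dt`.", bad),
      class = "lfcr_step_error"
    )
  }
  conc2 <- pmax(conc2, 0)

  cov2 <- min(1, cov + dt * params$biofilm_regrowth * (1 - cov) * HS / (params$K_HS + HS))
  g_per_mmol <- volume * MM[["sulphur"]] / 1000
  film_S2 <- state[["film_S"]] + dt * params$eta_S0 * r_ox * g_per_mmol
  film_mass2 <- film_S2 / film_frac_s
  gap_S2 <- state[["gap_S"]] + dt * (1 - params$eta_S0) * r_ox * g_per_mmol

  out <- state
  out[["time"]] <- state[["time"]] + dt
  out[c("sulphate", "sulphide", "lactate", "acetate", "propionate")] <- conc2
  out[["coverage"]] <- cov2
  out[["film_S"]] <- film_S2
  out[["film_mass"]] <- film_mass2
  out[["gap_S"]] <- gap_S2
  out[["cum_in_S"]] <- state[["cum_in_S"]] + dt * D * feed$sulphate_mmol_l * g_per_mmol
  out[["cum_out_S"]] <- state[["cum_out_S"]] + dt * D * (S + HS) * g_per_mmol
  out[["cum_out_HS_S"]] <- state[["cum_out_HS_S"]] + dt * D * HS * g_per_mmol
  out
}

#' Simulate a temperature-staged reactor run
#'
#' Runs the explicit mass balance of [reactor_step()] through the stages of
#' a [reactor_schedule()], applying biofilm disruption (surface coverage
#' reset; fragments settle onto the harvest screen) and biofilm harvest
#' (accumulated film mass and sulphur emitted as a harvest record and
#' reset) at their scheduled times, and drawing samples from four ports and
#' the effluent at the sampling interval. Port samples share the same truth
#' trajectory (the bulk is well mixed) and differ only by independent
#' multiplicative Gaussian measurement noise, clipped at zero.
#'
#' @param feed A [feed_spec()].
#' @param params A [kinetic_params()].
#' @param schedule A [reactor_schedule()].
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (0 disables noise).
#' @param seed Integer seed; identical seeds give identical output.
#' @param volume Reactor working volume (L).
#' @param dt Integration step (h).
#' @param film_composition Named mass fractions (`C`, `H`, `N`, `S`) of the
#'   dry harvested biofilm; the remainder is the inorganic (struvite-rich)
#'   fraction.
#'
#' @return An object of class `lfcr_sim`: a list with tibbles `samples`
#'   (noisy per-port records), `harvests`, `truth` (noiseless trajectory at
#'   sample times) and a `totals` list of cumulative sulphur pools (g) for
#'   mass-balance checks.
#' @examples
#' sim <- simulate_reactor(feed_spec(), kinetic_params(),
#'   reactor_schedule(stage_temps_c = 30, stage_duration_rt = 6),
#'   noise_cv = 0, seed = 1
#' )
#' dplyr::glimpse(sim$samples)
#' @export
simulate_reactor <- function(feed, params, schedule,
                             noise_cv = 0.05, seed = 1,
                             volume = 2, dt = 0.1,
                             film_composition = c(C = 0.11, H = 0.02, N = 0.02, S = 0.29)) {
  stopifnot(inherits(feed, "feed_spec"), inherits(params, "kinetic_params"),
            inherits(schedule, "reactor_schedule"))
  if (nrow(schedule$stages) == 0) {
    abort("Schedule has no stages.", class = "lfcr_config_error")
  }
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.", class = "lfcr_domain_error")
  fs <- film_composition[["S"]]
  if (sum(film_composition) > 1 + 1e-9 || any(film_composition < 0)) {
    abort("`film_composition` fractions must be non-negative and sum to at most 1.",
      class = "lfcr_domain_error")
  }

  ev <- schedule_events(schedule)
  n_steps <- round(ev$total_h / dt)
  if (abs(n_steps * dt - ev$total_h) > 1e-6) {
    abort("`dt` must divide the total schedule duration.", class = "lfcr_config_error")
  }
  step_of <- function(times) as.integer(round(times / dt))
  dis_steps <- step_of(ev$disruption)
  har_steps <- step_of(ev$harvest)
  samp_steps <- step_of(ev$sample)
  if (any(abs(samp_steps * dt - ev$sample) > 1e-6)) {
    abort("`dt` must divide the sampling interval.", class = "lfcr_config_error")
  }

  analytes <- c("sulphate", "sulphide", "lactate", "acetate", "propionate")
  state <- initial_state(feed)
  truth_rows <- matrix(NA_real_, nrow = length(samp_steps),
                       ncol = 2 + length(analytes) + 4)
  harvest_rows <- matrix(NA_real_, nrow = length(har_steps), ncol = 2)
  samp_i <- 0L; harv_i <- 0L

  for (i in seq_len(n_steps)) {
    t_mid <- (i - 0.5) * dt
    temp_c <- stage_temp_at(schedule, t_mid)
    state <- reactor_step(state, temp_c, feed, params, dt, schedule$hrt,
                          volume = volume, film_frac_s = fs)
    if (i %in% dis_steps) state[["coverage"]] <- 0
    if (i %in% har_steps) {
      harv_i <- harv_i + 1L
      harvest_rows[harv_i, ] <- c(i * dt, state[["film_mass"]])
      state[["harvested_S"]] <- state[["harvested_S"]] + state[["film_S"]]
      state[["harvested_mass"]] <- state[["harvested_mass"]] + state[["film_mass"]]
      state[["film_S"]] <- 0; state[["film_mass"]] <- 0
    }
    if (i %in% samp_steps) {
      samp_i <- samp_i + 1L
      truth_rows[samp_i, ] <- c(i * dt, stage_temp_at(schedule, t_mid), state[analytes],
                                state[["coverage"]], state[["film_S"]],
                                state[["film_mass"]], state[["gap_S"]])
    }
  }

  truth <- as_tibble(as.data.frame(truth_rows))
  names(truth) <- c("time_h", "temp_C", paste0(analytes, "_mmol_L"),
                    "coverage", "film_S_g", "film_mass_g", "gap_S_g")

  ports <- c("P1", "P2", "P3", "P4", "effluent")
  samples <- tidyr::crossing(port = ports, truth[c("time_h", "temp_C",
                                                  paste0(analytes, "_mmol_L"))]) |>
    dplyr::arrange(.data$time_h, .data$port) |>
    dplyr::relocate("time_h", "port", "temp_C")
  conc_cols <- paste0(analytes, "_mmol_L")
  if (noise_cv > 0) {
    n <- nrow(samples) * length(conc_cols)
    eps <- withr::with_seed(seed, rnorm(n, mean = 1, sd = noise_cv))
    noisy <- as.matrix(samples[conc_cols]) * matrix(eps, nrow = nrow(samples))
    samples[conc_cols] <- pmax(noisy, 0)
  }
  samples$port <- factor(samples$port, levels = ports)

  harvests <- tibble(
    time_h = harvest_rows[, 1],
    dry_mass_g = harvest_rows[, 2],
    frac_C = film_composition[["C"]],
    frac_H = film_composition[["H"]],
    frac_N = film_composition[["N"]],
    frac_S = film_composition[["S"]]
  )

  g_per_mmol <- volume * MM[["sulphur"]] / 1000
  totals <- list(
    influent_S_g = state[["cum_in_S"]],
    effluent_S_g = state[["cum_out_S"]],
    effluent_sulphide_S_g = state[["cum_out_HS_S"]],
    harvested_film_S_g = state[["harvested_S"]],
    reactor_film_S_g = state[["film_S"]],
    gap_S_g = state[["gap_S"]],
    initial_dissolved_S_g = feed$sulphate_mmol_l * g_per_mmol,
    final_dissolved_S_g = (state[["sulphate"]] + state[["sulphide"]]) * g_per_mmol,
    final_sulphide_S_g = state[["sulphide"]] * g_per_mmol
  )
  # sulphide produced over the run (g S), reconstructed from its sinks
  totals$reduced_S_g <- totals$harvested_film_S_g + totals$reactor_film_S_g +
    totals$gap_S_g + totals$final_sulphide_S_g + totals$effluent_sulphide_S_g

  structure(
    list(
      samples = samples, harvests = harvests, truth = truth, totals = totals,
      feed = feed, params = params, schedule = schedule,
      volume = volume, dt = dt, noise_cv = noise_cv, seed = seed,
      film_composition = film_composition
    ),
    class = "lfcr_sim"
  )
}

#' @export
print.lfcr_sim <- function(x, ...) {
  cat(sprintf(
    "<lfcr_sim> %d stages, %.0f h, %d sample records, %d harvests (seed %d, CV %.0f%%)\n",
    nrow(x$schedule$stages), max(x$truth$time_h), nrow(x$samples),
    nrow(x$harvests), x$seed, 100 * x$noise_cv
  ))
  invisible(x)
}

#' Sulphur mass-balance closure of a simulated run
#'
#' Checks atom conservation over the whole run: sulphur entering with the
#' feed plus the initial dissolved inventory must equal sulphur leaving
#' with the effluent, captured in harvested and standing film, accumulated
#' in the colloidal gap pool, and remaining dissolved.
#'
#' @param sim An `lfcr_sim` object.
#' @return A tibble with the pool masses (g), the absolute closure error
#'   and the error relative to total sulphur input.
#' @export
sulphur_closure <- function(sim) {
  tt <- sim$totals
  input <- tt$influent_S_g + tt$initial_dissolved_S_g
  output <- tt$effluent_S_g + tt$harvested_film_S_g + tt$reactor_film_S_g +
    tt$gap_S_g + tt$final_dissolved_S_g
  tibble(
    influent_S_g = tt$influent_S_g,
    initial_dissolved_S_g = tt$initial_dissolved_S_g,
    effluent_S_g = tt$effluent_S_g,
    harvested_film_S_g = tt$harvested_film_S_g,
    reactor_film_S_g = tt$reactor_film_S_g,
    gap_S_g = tt$gap_S_g,
    final_dissolved_S_g = tt$final_dissolved_S_g,
    closure_error_g = input - output,
    closure_error_rel = (input - output) / input
  )
}
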