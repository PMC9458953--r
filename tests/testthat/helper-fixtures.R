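# Shared fixtures and independent oracles used across test files.

# Short single-stage schedule (6 residence times at one temperature).
one_stage_schedule <- function(temp_c = 30, duration_rt = 6, hrt = 48) {
  reactor_schedule(
    hrt = hrt, stage_temps_c = temp_c, stage_duration_rt = duration_rt,
    disruption_interval = 3, harvest_interval = 6, sample_interval = 24
  )
}

# Temperature-independent kinetics (Arrhenius factor 1 everywhere).
flat_params <- function(k_max = 0.144, K_S = 0.1, ...) {
  kinetic_params(k_max = k_max, K_S = K_S, Ea_above = 0, Ea_below = 0, ...)
}

# Closed-form steady state of a Monod sink in a chemostat:
# positive root of D*(c_in - c) = k*c/(K + c).
monod_steady_state <- function(c_in, D, k, K) {
  # D*c^2 + (D*K - D*c_in + k)*c - D*K*c_in = 0
  a <- D
  b <- D * K - D * c_in + k
  cc <- -D * K * c_in
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# Arrhenius forward model: rate at temp_K for a law anchored at (T_ref, k_ref).
arrhenius_rate <- function(temp_K, k_ref, Ea, T_ref) {
  k_ref * exp(-Ea / 8.314 * (1 / temp_K - 1 / T_ref))
}

# Two-regime forward model continuous at t_crit_K.
two_regime_rate <- function(temp_K, k_ref, Ea_warm, Ea_cold, T_ref, t_crit_K) {
  k_crit <- arrhenius_rate(t_crit_K, k_ref, Ea_warm, T_ref)
  ifelse(temp_K >= t_crit_K,
    arrhenius_rate(temp_K, k_ref, Ea_warm, T_ref),
    arrhenius_rate(temp_K, k_crit, Ea_cold, t_crit_K)
  )
}

# Brute-force segmented-fit oracle: enumerate every contiguous split of the
# temperature-ordered points (>= 2 per side), fit both sides with lm and
# return the minimum pooled RSS (ties to the warmest boundary).
enumerate_split_oracle <- function(points) {
  pts <- points[order(-points$temp_K), ]
  n <- nrow(pts)
  best <- NULL
  for (i in 2:(n - 2)) {
    rss_of <- function(rows) {
      f <- lm(log(rate) ~ I(1 / temp_K), data = pts[rows, ])
      sum(residuals(f)^2)
    }
    rss <- rss_of(1:i) + rss_of((i + 1):n)
    if (is.null(best) || rss < best$rss - 1e-12 * max(1, best$rss)) {
      best <- list(i = i, rss = rss)
    }
  }
  best
}
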