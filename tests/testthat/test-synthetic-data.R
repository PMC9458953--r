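test_that("feed_spec derives molar sulphate and COD ratio, and validates input", {
  feed <- feed_spec()
  expect_equal(feed$sulphate_mmol_l, 1000 * 1 / 96.06, tolerance = 1e-12)
  expect_equal(feed$cod_to_sulphate, 10.94 * 96 / 1000, tolerance = 1e-12)
  acet <- feed_spec(carbon_source = "acetate")
  expect_equal(acet$carbon_mmol_l, 1000 * 0.92 / 82.03, tolerance = 1e-12)
  expect_error(feed_spec(sulphate_g_l = 0), class = "lfcr_domain_error")
  expect_error(feed_spec(carbon_mmol_l = -1), class = "lfcr_domain_error")
})

test_that("temperature factor is 1 at reference, matches direct evaluation, and is continuous", {
  p <- kinetic_params()
  expect_equal(temperature_factor(303.15, p), 1.0, tolerance = 1e-12)

  # direct evaluation of the warm law at 15 degC
  expected <- exp(-(19000 / 8.314) * (1 / 288.15 - 1 / 303.15))
  expect_equal(temperature_factor(288.15, p), expected, tolerance = 1e-9)
  expect_equal(expected, 0.6754, tolerance = 1e-4)

  # continuity at the critical temperature
  eps <- 1e-8
  expect_equal(
    temperature_factor(p$T_crit - eps, p),
    temperature_factor(p$T_crit + eps, p),
    tolerance = 1e-6
  )
  # steeper decline below T_crit
  ratio_above <- temperature_factor(p$T_crit, p) / temperature_factor(p$T_crit + 5, p)
  ratio_below <- temperature_factor(p$T_crit - 5, p) / temperature_factor(p$T_crit, p)
  expect_lt(ratio_below, ratio_above)
  expect_error(temperature_factor(-1, p), class = "lfcr_domain_error")
})

test_that("reactor_step leaves a zero-rate reactor at feed composition unchanged", {
  feed <- feed_spec(yeast_extract_acetate_rate = 0)
  p <- kinetic_params(k_max = 0, k_ox_max = 0, biofilm_regrowth = 0)
  s0 <- initial_state(feed)
  s1 <- reactor_step(s0, 30, feed, p, dt = 0.1, hrt = 48)
  for (v in c("sulphate", "sulphide", "lactate", "acetate", "propionate",
              "coverage", "film_S", "gap_S")) {
    expect_equal(s1[[v]], s0[[v]], tolerance = 1e-12, label = v)
  }
  expect_equal(s1[["time"]], 0.1)
})

test_that("reactor_step enforces the step-size guard and names an overshooting species", {
  feed <- feed_spec()
  p <- kinetic_params()
  s0 <- initial_state(feed)
  expect_error(reactor_step(s0, 30, feed, p, dt = 1, hrt = 48),
    class = "lfcr_domain_error")

  # violent sulphide sink plus dilution overshoots below zero at a legal dt
  p_fast <- kinetic_params(k_max = 0, k_ox_max = 500, K_HS = 1e-6)
  s0[["sulphide"]] <- 1
  expect_error(
    reactor_step(s0, 30, feed, p_fast, dt = 0.4, hrt = 48),
    regexp = "sulphide", class = "lfcr_step_error"
  )
})

test_that("steady state matches the zero-order closed form when sulphate saturates", {
  # S >> K_S and donor unlimited: conversion X = r / (D * c_in) = 0.664
  feed <- feed_spec(carbon_source = "acetate", carbon_mmol_l = 1000,
                    yeast_extract_acetate_rate = 0)
  p <- flat_params(k_max = 0.144, K_S = 1e-9, k_ox_max = 0, biofilm_regrowth = 0)
  sim <- simulate_reactor(feed, p, one_stage_schedule(30, duration_rt = 20),
                          noise_cv = 0, seed = 1)
  s_end <- tail(sim$truth$sulphate_mmol_L, 1)
  x <- conversion_efficiency(feed$sulphate_mmol_l, s_end)
  expect_equal(x, 0.144 * 48 / feed$sulphate_mmol_l, tolerance = 1e-4)
  expect_equal(x, 0.664, tolerance = 1e-3)
})

test_that("steady state matches the Monod quadratic root", {
  feed <- feed_spec(carbon_source = "acetate", carbon_mmol_l = 1000,
                    yeast_extract_acetate_rate = 0)
  k <- 0.144; K_S <- 0.8
  p <- flat_params(k_max = k, K_S = K_S, k_ox_max = 0, biofilm_regrowth = 0)
  sim <- simulate_reactor(feed, p, one_stage_schedule(30, duration_rt = 40),
                          noise_cv = 0, seed = 1)
  s_end <- tail(sim$truth$sulphate_mmol_L, 1)
  s_star <- monod_steady_state(feed$sulphate_mmol_l, 1 / 48, k, K_S)
  expect_equal(s_end, s_star, tolerance = 1e-6)
})

test_that("sulphur atoms are conserved over a full cooling schedule", {
  sim <- simulate_reactor(feed_spec(), kinetic_params(), reactor_schedule(),
                          noise_cv = 0, seed = 1)
  cl <- sulphur_closure(sim)
  expect_lt(abs(cl$closure_error_rel), 1e-6)
  # every pool is non-negative
  expect_true(all(unlist(cl[1, 1:7]) >= 0))
})

test_that("noiseless samples equal the truth trajectory and seeds give identical output", {
  feed <- feed_spec(); p <- kinetic_params()
  sch <- one_stage_schedule(25)
  sim0 <- simulate_reactor(feed, p, sch, noise_cv = 0, seed = 7)
  eff <- dplyr::filter(sim0$samples, port == "effluent")
  expect_equal(eff$sulphate_mmol_L, sim0$truth$sulphate_mmol_L, tolerance = 1e-12)
  expect_equal(eff$acetate_mmol_L, sim0$truth$acetate_mmol_L, tolerance = 1e-12)

  sim1 <- simulate_reactor(feed, p, sch, noise_cv = 0.05, seed = 11)
  sim2 <- simulate_reactor(feed, p, sch, noise_cv = 0.05, seed = 11)
  expect_identical(sim1$samples, sim2$samples)
  expect_identical(sim1$harvests, sim2$harvests)
  sim3 <- simulate_reactor(feed, p, sch, noise_cv = 0.05, seed = 12)
  expect_false(isTRUE(all.equal(sim1$samples, sim3$samples)))
})

test_that("coverage stays in [0,1] and concentrations stay non-negative throughout", {
  sim <- simulate_reactor(feed_spec(), kinetic_params(), reactor_schedule(),
                          noise_cv = 0.05, seed = 3)
  expect_true(all(sim$truth$coverage >= 0 & sim$truth$coverage <= 1))
  conc <- as.matrix(sim$truth[, grep("_mmol_L$", names(sim$truth))])
  expect_true(all(conc >= -1e-12))
  noisy <- as.matrix(sim$samples[, grep("_mmol_L$", names(sim$samples))])
  expect_true(all(noisy >= 0))
})

test_that("steady-state conversion is non-increasing as temperature decreases", {
  sim <- simulate_reactor(feed_spec(), kinetic_params(), reactor_schedule(),
                          noise_cv = 0, seed = 1)
  ss <- stage_summaries(sim$samples, sim$feed, sim$schedule)
  conv <- dplyr::filter(ss, compartment == "bulk")$conversion
  expect_true(all(diff(conv) <= 1e-9))
})

test_that("ASV tables close to the read depth and honour degenerate designs", {
  design <- asv_design(default_asv_taxa(), read_depth = 35000)
  tab <- generate_asv_table(design, temperatures = c(30, 10), seed = 5)
  counts <- tab[-(1:2)]
  expect_equal(unname(colSums(as.matrix(counts))), rep(35000, ncol(counts)))
  expect_equal(ncol(counts), 8) # 4 communities x 2 temperatures

  # identical seed, identical table
  expect_identical(tab, generate_asv_table(design, c(30, 10), seed = 5))

  # single taxon gets every read at any temperature
  one <- default_asv_taxa()[1, ]
  d1 <- asv_design(one, communities = "CF")
  t1 <- generate_asv_table(d1, temperatures = c(30, 10), seed = 1)
  expect_equal(unname(as.matrix(t1[-(1:2)])[1, ]), c(35000, 35000))
})

test_that("zero temperature sensitivity gives identical expected proportions across temperatures", {
  taxa <- default_asv_taxa()
  taxa$sensitivity <- 0
  design <- asv_design(taxa)
  p30 <- lfcrtemp:::asv_expected_proportions(design, "CF", 30)
  p10 <- lfcrtemp:::asv_expected_proportions(design, "CF", 10)
  expect_equal(p30, p10, tolerance = 1e-12)
  expect_equal(sum(p30), 1, tolerance = 1e-12)
})
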