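test_that("conversion efficiency covers the full range and clips with a warning", {
  expect_equal(conversion_efficiency(10.41, 10.41), 0)
  expect_equal(conversion_efficiency(10.41, 0), 1)
  expect_equal(conversion_efficiency(10.41, 3.54), (10.41 - 3.54) / 10.41,
               tolerance = 1e-12)
  expect_equal(conversion_efficiency(10.41, 3.54), 0.660, tolerance = 1e-3)
  expect_warning(x <- conversion_efficiency(10, 12))
  expect_equal(x, 0)
  expect_error(conversion_efficiency(0, 1), class = "lfcr_domain_error")
})

test_that("volumetric rate and VSOR follow their defining arithmetic", {
  expect_equal(volumetric_rate(0, 10.41, 48), 0)
  expect_equal(volumetric_rate(0.66, 10.41, 48), 0.66 * 10.41 / 48, tolerance = 1e-12)
  expect_error(volumetric_rate(0.5, 10.41, 0), class = "lfcr_domain_error")

  expect_equal(vsor_estimate(2.81, 2.81, 48), 0)
  expect_equal(vsor_estimate(2.81, 1.50, 48), (2.81 - 1.50) / 48, tolerance = 1e-12)
  expect_equal(vsor_estimate(2.81, 1.50, 48), 0.0273, tolerance = 1e-3)
  expect_warning(v <- vsor_estimate(1, 2, 48))
  expect_equal(v, 0)
  expect_error(vsor_estimate(1, 0.5, -1), class = "lfcr_domain_error")
})

test_that("stage summaries reproduce hand-computed rates on a constant table", {
  feed <- feed_spec()
  sch <- one_stage_schedule(30, duration_rt = 3)
  # constant concentrations across the stage: sulphate 4, sulphide 2,
  # lactate 1, acetate 3, propionate 1.2 mmol/L
  grid <- tidyr::crossing(
    time_h = c(96, 120, 144),
    port = c("P1", "P2", "P3", "P4", "effluent")
  )
  records <- dplyr::mutate(grid,
    temp_C = 30, sulphate_mmol_L = 4, sulphide_mmol_L = 2,
    lactate_mmol_L = 1, acetate_mmol_L = 3, propionate_mmol_L = 1.2
  )
  ss <- stage_summaries(records, feed, sch)
  bulk <- dplyr::filter(ss, compartment == "bulk")
  cf <- feed$sulphate_mmol_l
  expect_equal(bulk$conversion, (cf - 4) / cf, tolerance = 1e-12)
  expect_equal(bulk$vsrr_mmol_L_h, (cf - 4) / 48, tolerance = 1e-12)
  expect_equal(bulk$expected_sulphide_mmol_L, cf - 4, tolerance = 1e-12)
  expect_equal(bulk$vsor_mmol_L_h, (cf - 4 - 2) / 48, tolerance = 1e-12)
  expect_equal(bulk$lactate_util_mmol_L_h, (10.94 - 1) / 48, tolerance = 1e-12)
  expect_equal(bulk$acetate_prod_mmol_L_h, 3 / 48, tolerance = 1e-12)
  expect_equal(bulk$propionate_prod_mmol_L_h, 1.2 / 48, tolerance = 1e-12)
  expect_equal(bulk$n_samples, 12L) # 4 ports x 3 times
  eff <- dplyr::filter(ss, compartment == "effluent")
  expect_equal(eff$n_samples, 3L)

  # constant records equal to feed give all-zero rates
  at_feed <- dplyr::mutate(grid,
    temp_C = 30, sulphate_mmol_L = feed$sulphate_mmol_l, sulphide_mmol_L = 0,
    lactate_mmol_L = feed$carbon_mmol_l, acetate_mmol_L = 0, propionate_mmol_L = 0
  )
  z <- dplyr::filter(stage_summaries(at_feed, feed, sch), compartment == "bulk")
  expect_equal(z$vsrr_mmol_L_h, 0, tolerance = 1e-12)
  expect_equal(z$lactate_util_mmol_L_h, 0, tolerance = 1e-12)
  expect_equal(z$acetate_prod_mmol_L_h, 0, tolerance = 1e-12)
})

test_that("a stage without samples raises a missing-stage error", {
  feed <- feed_spec()
  sch <- reactor_schedule(stage_temps_c = c(30, 25), stage_duration_rt = 3)
  records <- tibble::tibble(
    time_h = 144, port = "P1", temp_C = 30, sulphate_mmol_L = 4,
    sulphide_mmol_L = 1, lactate_mmol_L = 1, acetate_mmol_L = 1,
    propionate_mmol_L = 0.5
  )
  expect_error(stage_summaries(records, feed, sch),
    class = "lfcr_missing_stage_error")
})

test_that("summary identities hold and VSOR is bounded by its zero-sulphide limit", {
  sim <- simulate_reactor(feed_spec(), kinetic_params(), reactor_schedule(),
                          noise_cv = 0.05, seed = 2)
  ss <- stage_summaries(sim$samples, sim$feed, sim$schedule)
  cf <- sim$feed$sulphate_mmol_l
  expect_equal(ss$vsrr_mmol_L_h, ss$conversion * cf / 48, tolerance = 1e-9)
  expect_equal(ss$expected_sulphide_mmol_L, ss$conversion * cf, tolerance = 1e-9)
  expect_true(all(ss$vsor_mmol_L_h <= ss$conversion * cf / 48 + 1e-12))
})

test_that("calibrated simulator endpoints reproduce the lactate-fed operating rates", {
  sim <- simulate_reactor(feed_spec(), kinetic_params(), reactor_schedule(),
                          noise_cv = 0, seed = 1)
  bulk <- dplyr::filter(stage_summaries(sim$samples, sim$feed, sim$schedule),
                        compartment == "bulk")
  vsrr_30 <- bulk$vsrr_mmol_L_h[bulk$temp_C == 30]
  vsrr_10 <- bulk$vsrr_mmol_L_h[bulk$temp_C == 10]
  expect_equal(vsrr_30, 0.144, tolerance = 0.05)
  expect_equal(vsrr_10, 0.059, tolerance = 0.05)
  # lactate supply is the cap at 30 degC: utilisation approaches 0.228 mmol/L.h
  expect_equal(bulk$lactate_util_mmol_L_h[bulk$temp_C == 30], 0.228, tolerance = 0.01)
})

test_that("noisy stage rates recover the noiseless ones within 10%", {
  feed <- feed_spec(); p <- kinetic_params(); sch <- reactor_schedule()
  truth <- dplyr::filter(
    stage_summaries(simulate_reactor(feed, p, sch, noise_cv = 0, seed = 1)$samples,
                    feed, sch),
    compartment == "bulk")
  noisy <- dplyr::filter(
    stage_summaries(simulate_reactor(feed, p, sch, noise_cv = 0.05, seed = 4)$samples,
                    feed, sch),
    compartment == "bulk")
  rel <- abs(noisy$vsrr_mmol_L_h - truth$vsrr_mmol_L_h) / truth$vsrr_mmol_L_h
  expect_true(all(rel < 0.10))
})
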