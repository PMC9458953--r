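test_that("a two-point segment is exact and recovers the generating activation energy", {
  k30 <- 0.144
  k15 <- arrhenius_rate(288.15, k30, 19000, 303.15)
  seg <- fit_arrhenius_segment(tibble::tibble(temp_K = c(303.15, 288.15),
                                              rate = c(k30, k15)))
  expect_equal(seg$Ea, 19000, tolerance = 1e-9)
  expect_equal(seg$r_squared, 1)
  expect_equal(k15, 0.0973, tolerance = 1e-3)
})

test_that("multi-point noiseless data invert the forward model exactly", {
  temps <- c(30, 25, 20, 15) + 273.15
  pts <- tibble::tibble(temp_K = temps,
                        rate = arrhenius_rate(temps, 0.127, 50400, 303.15))
  seg <- fit_arrhenius_segment(pts)
  expect_equal(seg$Ea, 50400, tolerance = 1e-9)
  expect_equal(seg$r_squared, 1, tolerance = 1e-12)
})

test_that("flat rates give zero activation energy and edge cases error or warn", {
  pts <- tibble::tibble(temp_C = c(30, 20, 10), rate = 0.1)
  seg <- fit_arrhenius_segment(pts)
  expect_equal(seg$Ea, 0, tolerance = 1e-9)

  expect_warning(
    seg2 <- fit_arrhenius_segment(
      tibble::tibble(temp_C = c(30, 20, 10), rate = c(0.1, 0.05, 0))),
    regexp = "non-positive"
  )
  expect_equal(seg2$n, 2)
  expect_error(
    suppressWarnings(fit_arrhenius_segment(
      tibble::tibble(temp_C = c(30, 20), rate = c(0.1, 0)))),
    class = "lfcr_insufficient_data_error"
  )
})

test_that("Ea is invariant to rescaling rates by a positive constant", {
  temps <- c(303.15, 298.15, 293.15, 288.15)
  rate <- arrhenius_rate(temps, 0.144, 19000, 303.15) * exp(rnorm(4, sd = 0.01))
  s1 <- fit_arrhenius_segment(tibble::tibble(temp_K = temps, rate = rate))
  s2 <- fit_arrhenius_segment(tibble::tibble(temp_K = temps, rate = 7.3 * rate))
  expect_equal(s1$Ea, s2$Ea, tolerance = 1e-9)
  expect_equal(s1$r_squared, s2$r_squared, tolerance = 1e-9)
})

test_that("segment intersection recovers a constructed critical temperature", {
  # warm law anchored at 30 degC; cold law continues from it below 15 degC
  warm_pts <- tibble::tibble(
    temp_K = c(303.15, 293.15),
    rate = arrhenius_rate(c(303.15, 293.15), 0.144, 19000, 303.15)
  )
  k_crit <- arrhenius_rate(288.15, 0.144, 19000, 303.15)
  cold_pts <- tibble::tibble(
    temp_K = c(283.15, 278.15),
    rate = arrhenius_rate(c(283.15, 278.15), k_crit, 65700, 288.15)
  )
  warm <- fit_arrhenius_segment(warm_pts)
  cold <- fit_arrhenius_segment(cold_pts)
  expect_equal(intersect_segments(warm, cold), 288.15, tolerance = 1e-6)
  # symmetric in the segment labels
  expect_equal(intersect_segments(cold, warm), intersect_segments(warm, cold),
               tolerance = 1e-9)
  # the cold law evaluated at 10 degC gives the low-temperature endpoint rate
  expect_equal(arrhenius_rate(283.15, k_crit, 65700, 288.15), 0.0599,
               tolerance = 1e-3)
  # parallel segments have no intersection
  expect_error(intersect_segments(warm, warm), class = "lfcr_parallel_error")
})

test_that("fixed-split fits share the boundary point and predict piecewise", {
  temps_c <- c(30, 25, 20, 15, 10)
  temps_k <- temps_c + 273.15
  pts <- tibble::tibble(temp_C = temps_c,
                        rate = two_regime_rate(temps_k, 0.144, 19000, 65700,
                                               303.15, 288.15))
  fit <- arrhenius_fit(pts, mode = "fixed", boundary_temp_c = 15)
  expect_equal(fit$segment_warm$n, 4)
  expect_equal(fit$segment_cold$n, 2)
  expect_equal(fit$segment_warm$Ea, 19000, tolerance = 1e-6)
  expect_equal(fit$segment_cold$Ea, 65700, tolerance = 1e-6)
  expect_equal(fit$t_crit_K, 288.15, tolerance = 1e-6)

  # prediction continuity at the intersection: both segment lines agree there
  at_crit <- 1 / fit$t_crit_K
  expect_equal(
    exp(fit$segment_warm$intercept + fit$segment_warm$slope * at_crit),
    exp(fit$segment_cold$intercept + fit$segment_cold$slope * at_crit),
    tolerance = 1e-9
  )
  eps <- 1e-7
  expect_equal(predict(fit, fit$t_crit_C + eps), predict(fit, fit$t_crit_C - eps),
               tolerance = 1e-6)
  # warm-side predictions reproduce the inputs; cold side too
  expect_equal(predict(fit, temps_c), pts$rate, tolerance = 1e-9)

  expect_error(arrhenius_fit(pts, mode = "fixed", boundary_temp_c = 17),
    class = "lfcr_config_error")
})

test_that("auto mode recovers a generating two-regime partition and T_crit", {
  temps_c <- c(30, 25, 20, 15, 10, 5)
  temps_k <- temps_c + 273.15
  pts <- tibble::tibble(temp_C = temps_c,
                        rate = two_regime_rate(temps_k, 0.144, 19000, 65700,
                                               303.15, 288.15))
  fit <- arrhenius_fit(pts, mode = "auto")
  # the 15 degC break point lies on both laws, so both zero-RSS partitions
  # are valid; the tie-break takes the warmer boundary, and the recovered
  # laws and critical temperature are exact either way
  expect_equal(glance(fit)$pooled_rss, 0, tolerance = 1e-12)
  expect_equal(fit$segment_warm$Ea, 19000, tolerance = 1e-6)
  expect_equal(fit$segment_cold$Ea, 65700, tolerance = 1e-6)
  expect_equal(fit$t_crit_K, 288.15, tolerance = 0.1)
})

test_that("auto mode on single-regime data degenerates to two equal segments", {
  temps_k <- c(30, 25, 20, 15, 10) + 273.15
  pts <- tibble::tibble(temp_K = temps_k,
                        rate = arrhenius_rate(temps_k, 0.144, 19000, 303.15))
  single <- arrhenius_fit(pts, mode = "single")
  expect_warning(fit <- arrhenius_fit(pts, mode = "auto"), regexp = "parallel")
  expect_equal(fit$segment_warm$Ea, fit$segment_cold$Ea, tolerance = 1e-6)
  expect_true(is.na(fit$t_crit_K))
  expect_equal(glance(fit)$pooled_rss, single$segment_warm$rss, tolerance = 1e-12)
  # with no critical temperature the model predicts from the warm law
  expect_equal(predict(fit, 20), arrhenius_rate(293.15, 0.144, 19000, 303.15),
               tolerance = 1e-9)
})

test_that("auto mode equals the exhaustive-enumeration RSS oracle for small n", {
  withr::with_seed(99, {
    for (rep in 1:12) {
      n <- sample(4:8, 1)
      temps_k <- sort(sample(seq(278.15, 308.15, by = 2.5), n)) # distinct temps
      true_break <- sample(temps_k[2:(n - 1)], 1)
      rate <- two_regime_rate(temps_k, 0.15, 25000, 70000, 303.15, true_break) *
        exp(rnorm(n, sd = 0.05))
      pts <- tibble::tibble(temp_K = temps_k, rate = rate)
      fit <- suppressWarnings(arrhenius_fit(pts, mode = "auto"))
      oracle <- enumerate_split_oracle(pts)
      expect_equal(glance(fit)$pooled_rss, oracle$rss, tolerance = 1e-9)
      expect_equal(fit$segment_warm$n, oracle$i)
    }
  })
})

test_that("median recovered Ea under 5% multiplicative noise is within 5% of truth", {
  temps_k <- c(30, 25, 20, 15, 10) + 273.15
  truth <- arrhenius_rate(temps_k, 0.144, 50000, 303.15)
  est <- withr::with_seed(42, vapply(1:200, function(i) {
    noisy <- truth * exp(rnorm(5, sd = 0.05))
    fit_arrhenius_segment(tibble::tibble(temp_K = temps_k, rate = noisy))$Ea
  }, numeric(1)))
  expect_lt(abs(median(est) - 50000) / 50000, 0.05)
})

test_that("R^2 is exactly 1 for collinear points", {
  temps_k <- c(302, 296, 290, 284)
  pts <- tibble::tibble(temp_K = temps_k,
                        rate = exp(5 - 3000 / temps_k))
  expect_equal(fit_arrhenius_segment(pts)$r_squared, 1, tolerance = 1e-12)
})
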