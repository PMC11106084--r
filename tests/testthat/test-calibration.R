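test_that("linear dilution calibration recovers exact and noisy slopes", {
  d <- c(1, 0.5, 0.25, 0.125)
  exact <- data.frame(dilution = d, response = 7 * d)
  fit <- fit_linear_calibration(exact)
  expect_equal(fit$slope, 7, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(predict_calibration(fit, 0.5), 3.5, tolerance = 1e-12)

  # Poisson counts around a linear truth: 5 fields x 4 dilutions
  set.seed(42)
  truth_slope <- 400
  pairs <- expand.grid(dilution = d, field = 1:5)
  pairs$response <- rpois(nrow(pairs), truth_slope * pairs$dilution)
  nf <- fit_linear_calibration(pairs)
  expect_lt(abs(nf$slope - truth_slope), 3 * nf$slope_se)
  expect_gt(nf$r2, 0.9)

  expect_error(fit_linear_calibration(
    data.frame(dilution = c(0.5, 0.5, 0.5), response = 1:3)), "distinct")
  expect_error(fit_linear_calibration(
    data.frame(dilution = c(0, 0.5, 1), response = 1:3)), "\\(0, 1\\]")
})

test_that("pit counts convert to hits and dose with quadrature-combined errors", {
  conv <- default_conversion()
  zero <- pits_to_hits_and_dose(0, conv)
  expect_equal(zero$hits, 0)
  expect_equal(zero$dose_Gy, 0)
  hd <- pits_to_hits_and_dose(4.7, conv, pits_sd = 1.1)
  expect_equal(hd$hits, 4.7 * conv$hits_per_pit)
  expect_equal(hd$dose_Gy, 4.7 * conv$dose_per_pit_Gy)
  rel <- sqrt((1.1 / 4.7)^2 + (conv$dose_per_pit_se / conv$dose_per_pit_Gy)^2)
  expect_equal(hd$dose_sd, hd$dose_Gy * rel, tolerance = 1e-12)
  expect_error(pits_to_hits_and_dose(-1, conv), ">= 0")
})

test_that("delta-method SD of the converted dose matches a parametric bootstrap", {
  conv <- default_conversion()
  hd <- pits_to_hits_and_dose(4.7, conv, pits_sd = 1.1)
  set.seed(7)
  n <- 1e5
  draws <- rnorm(n, 4.7, 1.1) * rnorm(n, conv$dose_per_pit_Gy,
                                      conv$dose_per_pit_se)
  expect_equal(hd$dose_sd, sd(draws), tolerance = 0.05)
})

test_that("exponential survival fit inverts exact curves and round-trips", {
  doses <- c(0.2, 0.5, 0.8, 1.1)
  pts <- data.frame(dose = doses, sf = exp(-2 * doses))
  fit <- fit_exponential_survival(pts)
  expect_equal(fit$k, 2, tolerance = 1e-12)
  expect_equal(fit$D0, 0.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # round trip: predictions reproduce the generating curve exactly
  dd <- seq(0, 2, by = 0.25)
  expect_equal(predict_sf(fit, dd), exp(-2 * dd), tolerance = 1e-12)
  expect_equal(predict_sf(fit, 0), 1)
  expect_equal(predict_sf(fit, fit$D0), exp(-1), tolerance = 1e-12)
})

test_that("survival fits on the pit axis and dose axis are unit-coherent", {
  conv <- default_conversion()
  pits <- c(2, 4.7, 7, 9.4)
  sf <- exp(-1.1 * pits)
  on_pits <- fit_exponential_survival(data.frame(dose = pits, sf = sf))
  on_dose <- fit_exponential_survival(
    data.frame(dose = pits * conv$dose_per_pit_Gy, sf = sf))
  expect_equal(on_pits$k, on_dose$k * conv$dose_per_pit_Gy,
               tolerance = 1e-10)
})

test_that("D0 is recovered from noisy survival points", {
  k_true <- 5.09
  doses <- c(0.2, 0.4, 0.6, 0.8, 1.1)
  set.seed(314)
  rel_err <- replicate(100, {
    sf <- pmin(exp(-k_true * doses + rnorm(5, 0, 0.2)), 1)
    fit <- fit_exponential_survival(data.frame(dose = doses, sf = sf))
    abs(fit$D0 - 1 / k_true) / (1 / k_true)
  })
  expect_lt(median(rel_err), 0.05)
  expect_gte(mean(rel_err < 0.15), 0.9)
})

test_that("survival-fit input validation rejects degenerate data", {
  expect_error(fit_exponential_survival(
    data.frame(dose = c(1, 2, 3), sf = c(0.5, 0, 0.1))), "> 0")
  expect_error(fit_exponential_survival(
    data.frame(dose = c(1, 1, 1), sf = c(0.5, 0.4, 0.3))), "identical")
  expect_error(fit_exponential_survival(
    data.frame(dose = c(1, 2), sf = c(0.5, 0.2))), "at least 3")
})

test_that("average dose rate is total dose over duration", {
  expect_equal(average_dose_rate(1.10, 1440), 1.10 / 1440)
  expect_equal(signif(average_dose_rate(1.10, 1440), 2), 7.6e-4)
  expect_equal(average_dose_rate(0, 60), 0)
  expect_equal(signif(average_dose_rate(2.20, 1440), 3), 1.53e-3)
  expect_error(average_dose_rate(1, 0), "positive")
})

test_that("colony-formation surviving fractions follow the plating efficiency", {
  expect_equal(colony_survival(200, 100, 0.5)$sf, 1.0)
  expect_equal(colony_survival(10000, 37, 1.0)$sf, 0.0037)
  # synthetic assay at known truth: estimate within 3 binomial SE
  set.seed(5)
  sf_true <- 0.01; pe <- 0.6; plated <- 50000
  col <- rbinom(1, plated, pe * sf_true)
  est <- colony_survival(plated, col, pe)
  expect_lt(abs(est$sf - sf_true), 3 * est$sf_se)
  expect_error(colony_survival(0, 0, 0.5), "plated")
  expect_error(colony_survival(100, 10, 0), "efficiency")
  expect_error(colony_survival(100, 200, 0.5), "colonies")
})
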