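test_that("Schmidt number matches the hand-evaluated polynomial and decreases with T", {
  # 4th-order seawater polynomial evaluated by hand at 20 degC
  expect_equal(schmidt_number(20, 35), 686.6208, tolerance = 1e-6)
  expect_equal(schmidt_number(20, 0), 616.6192, tolerance = 1e-6)
  # brackish water interpolates linearly between the two fits
  expect_equal(schmidt_number(20, 17.5), (686.6208 + 616.6192) / 2,
               tolerance = 1e-6)
  temps <- seq(0, 30, by = 2)
  expect_true(all(diff(schmidt_number(temps, 35)) < 0))
  expect_gt(schmidt_number(15, 35), schmidt_number(20, 35))
  expect_error(schmidt_number(45, 35), "validity")
})

test_that("gas transfer velocity follows the printed parameterization", {
  expect_equal(gas_transfer_velocity(4, 660), 1.004)    # unity Schmidt ratio
  expect_equal(gas_transfer_velocity(0, 660), 0)
  expect_equal(gas_transfer_velocity(4, 660, mode = "quadratic"),
               0.251 * 16)
  # k continuous and increasing in U10
  u <- seq(0, 15, by = 0.5)
  expect_true(all(diff(gas_transfer_velocity(u, 686.6)) > 0))
  expect_error(gas_transfer_velocity(-1, 660), "non-negative")
})

test_that("sea-air flux vanishes at equilibrium and is linear in disequilibrium", {
  atm <- atmosphere_spec()
  ceq <- equilibrium_concentration(20, 35, atm$f_gas)
  f0 <- sea_air_flux(ceq, 20, 35, u10 = 5, atm = atm)
  expect_equal(f0$flux_mg_m2_d, 0, tolerance = 1e-12)
  f1 <- sea_air_flux(ceq + 10e-9, 20, 35, u10 = 5, atm = atm)
  f2 <- sea_air_flux(ceq + 20e-9, 20, 35, u10 = 5, atm = atm)
  expect_equal(f2$flux_mg_m2_d, 2 * f1$flux_mg_m2_d)
})

test_that("concentration and partial-pressure flux forms agree by construction", {
  atm <- atmosphere_spec()
  for (conc in c(5e-9, 100e-9, 5e-6)) {
    fc <- sea_air_flux(conc, 18, 33, 6, atm = atm, form = "concentration")
    fp <- sea_air_flux(conc, 18, 33, 6, atm = atm, form = "partial-pressure")
    expect_equal(fp$flux_mg_m2_d, fc$flux_mg_m2_d, tolerance = 1e-10)
  }
})

test_that("the synthetic flux case reproduces a one-line hand calculation", {
  # C = 100 nM, U10 = 4 m/s, 20 degC, S = 35, southern-hemisphere baseline
  atm <- atmosphere_spec(ppb = 1870)
  got <- sea_air_flux(100e-9, 20, 35, 4, atm = atm)
  k <- 0.251 * 4 * (686.6208 / 660)^-0.5              # cm/h
  ceq <- equilibrium_concentration(20, 35, 1.87e-6)   # mol/L
  oracle <- k / 100 / 3600 * (100e-9 - ceq) * 1000 * 16.04 * 1000 * 86400
  expect_equal(got$flux_mg_m2_d, oracle, tolerance = 1e-9)
  expect_equal(oracle, 0.37032269, tolerance = 1e-6)  # frozen
})

test_that("flux bounds equal brute-force enumeration over the raw records", {
  sv <- generate_survey(survey_scenario(n_sites = 8), seed = 11)
  wind <- generate_wind(11)$u10_m_s
  atm <- atmosphere_spec()
  b <- flux_bounds(sv, wind, atm = atm)
  # independent brute force: enumerate records, pick extremes by hand
  qs <- as.numeric(quantile(wind, c(0.25, 0.5, 0.75), type = 7))
  lo <- sv[which.min(sv$ch4_nM), ]
  hi <- sv[which.max(sv$ch4_nM), ]
  oracle <- c(
    sea_air_flux(lo$ch4_nM * 1e-9, lo$temp_C, lo$salinity, qs[1],
                 atm = atm)$flux_mg_m2_d,
    sea_air_flux(mean(sv$ch4_nM) * 1e-9, mean(sv$temp_C), mean(sv$salinity),
                 qs[2], atm = atm)$flux_mg_m2_d,
    sea_air_flux(hi$ch4_nM * 1e-9, hi$temp_C, hi$salinity, qs[3],
                 atm = atm)$flux_mg_m2_d)
  expect_equal(b$flux_mg_m2_d, oracle)
  expect_true(all(diff(b$flux_mg_m2_d) > 0)) # low <= mid <= high
  expect_identical(attr(b, "quantile_type"), 7L)
})

test_that("degenerate surveys give degenerate flux bounds", {
  one <- data.frame(ch4_nM = rep(50, 4), temp_C = 20, salinity = 35)
  b <- flux_bounds(one, rep(5, 10))
  expect_equal(b$flux_mg_m2_d[1], b$flux_mg_m2_d[2])
  expect_equal(b$flux_mg_m2_d[2], b$flux_mg_m2_d[3])
  # every record exactly at 100% saturation -> all three fluxes zero
  atm <- atmosphere_spec()
  ceq_nM <- equilibrium_concentration(20, 35, atm$f_gas) * 1e9
  eq <- data.frame(ch4_nM = rep(ceq_nM, 5), temp_C = 20, salinity = 35)
  b0 <- flux_bounds(eq, c(2, 4, 6, 8), atm = atm)
  expect_equal(b0$flux_mg_m2_d, rep(0, 3), tolerance = 1e-12)
  expect_error(flux_bounds(eq[0, ], 1:5), "empty")
})

test_that("radon decay correction follows the 222Rn half-life", {
  expect_equal(radon_decay_correct(100, 0), 100)
  expect_equal(radon_decay_correct(100, 3.8235), 200)     # one half-life
  expect_equal(radon_decay_correct(100, 1), 100 * exp(log(2) / 3.8235))
  expect_true(all(radon_decay_correct(c(10, 50), 2) >= c(10, 50)))
  expect_error(radon_decay_correct(100, -1), "non-negative")
})

test_that("methane-radon correlation matches a textbook hand computation", {
  ch4 <- c(12, 30, 25, 80, 41)
  rn <- c(55, 40, 62, 48, 51)
  # hand computation via explicit sums
  n <- 5
  r_hand <- (sum(ch4 * rn) - n * mean(ch4) * mean(rn)) /
    ((n - 1) * sd(ch4) * sd(rn))
  got <- ch4_radon_correlation(ch4, rn)
  expect_equal(got$r, r_hand)
  expect_equal(got$n, 5)
})
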