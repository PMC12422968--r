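cfg <- ftr_config(volume_cm3 = 50, area_cm2 = 25, flow_mL_h = 45)

test_that("volumetric rate implements the plug-flow balance", {
  ts <- data.frame(time_h = 0:2, c_in_uM = 1, c_out_uM = c(1, 2, 1))
  r <- volumetric_rate(ts, cfg)
  expect_equal(r$rate_umol_cm3_h, c(0, 45 * 1 * 1e-3 / 50, 0))
  expect_equal(r$rate_umol_cm3_h[2], 0.0009)
  # doubling flow doubles the rate at fixed concentrations
  ts$q_mL_h <- 90
  expect_equal(volumetric_rate(ts, cfg)$rate_umol_cm3_h[2], 0.0018)
  # consumption is permitted and flagged
  ts2 <- data.frame(time_h = 0, c_in_uM = 5, c_out_uM = 1, q_mL_h = 45)
  r2 <- volumetric_rate(ts2, cfg)
  expect_lt(r2$rate_umol_cm3_h, 0)
  expect_true(r2$consumption)
  expect_error(volumetric_rate(data.frame(time_h = c(2, 1), c_in_uM = 1,
                                          c_out_uM = 1), cfg),
               "time-ordered")
  expect_error(volumetric_rate(data.frame(time_h = 0, c_in_uM = -1,
                                          c_out_uM = 1), cfg),
               "non-negative")
})

test_that("areal flux reproduces the worked-example chain and is additive in depth", {
  a <- areal_flux(48, depth_cm = 0.5, molar_mass_g = 16.04)
  expect_equal(a$umol_cm2_h, 24.0)
  expect_equal(a$mmol_m2_h, 240)
  expect_equal(round(a$g_m2_h, 1), 3.8)
  # additivity: integrating 0.3 + 0.2 cm equals integrating 0.5 cm
  a1 <- areal_flux(48, 0.3)
  a2 <- areal_flux(48, 0.2)
  expect_equal(a1$g_m2_h + a2$g_m2_h, a$g_m2_h)
  expect_error(areal_flux(48, 0), "positive")
})

test_that("volumetric rate recovers the programmed rate of a simulated reactor", {
  scen <- reactor_scenario(noise_cv = 0)
  sim <- generate_reactor(scen, cfg, seed = 5, times_h = seq(0, 72, by = 2))
  r <- volumetric_rate(sim$ch4, cfg)
  # steady state (well past onset + logistic growth): within 1%
  late <- r$time_h >= 64
  expect_true(all(abs(r$rate_umol_cm3_h[late] / 48 - 1) < 0.01))
  # full trajectory matches the generator's programmed schedule
  expect_equal(r$rate_umol_cm3_h, sim$rate_ch4, tolerance = 1e-10)
})

test_that("CH4:CO2 ratio is definitional and follows the programmed trajectory", {
  eq <- data.frame(time_h = 0:3, c_in_uM = 0, c_out_uM = 2)
  expect_equal(ch4_co2_ratio(eq, eq, cfg)$ratio_n, rep(1, 4))
  nine <- data.frame(time_h = 0:3, c_in_uM = 0, c_out_uM = 18)
  expect_equal(ch4_co2_ratio(eq, nine, cfg)$ratio_n, rep(9, 4))
  # zero CH4 rate is flagged undefined, not an error
  z <- data.frame(time_h = 0:3, c_in_uM = 1, c_out_uM = 1)
  rz <- ch4_co2_ratio(z, nine, cfg)
  expect_true(all(rz$undefined))
  expect_true(all(is.na(rz$ratio_n)))
  # synthetic co-registered series reproduce the generator's ratio curve
  scen <- reactor_scenario(noise_cv = 0)
  sim <- generate_reactor(scen, cfg, seed = 2)
  rr <- ch4_co2_ratio(sim$ch4, sim$dic, cfg)
  ok <- !rr$undefined
  expect_equal(rr$ratio_n[ok], (sim$rate_dic / sim$rate_ch4)[ok],
               tolerance = 1e-9)
  expect_equal(rr$ratio_n[rr$time_h == 44], 9, tolerance = 1e-9)
})

test_that("slurry rate fitting recovers slopes with honest standard errors", {
  t <- seq(0, 18, by = 2)
  fit <- slurry_rate(t, 1 + 0.5 * t)
  expect_equal(fit$rate_umol_h, 0.5)
  expect_equal(fit$se_umol_h, 0, tolerance = 1e-12)
  expect_equal(slurry_rate(t, rep(2, length(t)))$rate_umol_h, 0)
  expect_error(slurry_rate(c(0, 1), c(0, 1)), "3 points")
  # coverage: with sigma known, the true slope lies within 3 true SEs in
  # >= 99% of seeded noisy series (n = 10)
  sigma <- 0.4
  se_true <- sigma / sqrt(sum((t - mean(t))^2))
  set.seed(42)
  hits <- vapply(seq_len(1000), function(i) {
    y <- 0.5 * t + rnorm(10, 0, sigma)
    abs(slurry_rate(t, y)$rate_umol_h - 0.5) <= 3 * se_true
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("maximum rate is reported both pointwise and windowed", {
  scen <- reactor_scenario(noise_cv = 0.05)
  sim <- generate_reactor(scen, cfg, seed = 9)
  m <- max_rate(volumetric_rate(sim$ch4, cfg))
  expect_gte(m$max_pointwise, m$max_windowed)
  expect_equal(m$max_windowed, 48, tolerance = 0.15)
})
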