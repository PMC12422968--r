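test_that("every generator is a pure function of (scenario, seed)", {
  sc <- survey_scenario()
  expect_identical(generate_survey(sc, 7), generate_survey(sc, 7))
  expect_false(identical(generate_survey(sc, 7)$ch4_nM,
                         generate_survey(sc, 8)$ch4_nM))
  expect_identical(generate_wind(3), generate_wind(3))
  v <- slurry_vial()
  expect_identical(generate_slurry(0.5, v, seed = 4, noise_rel = 0.01),
                   generate_slurry(0.5, v, seed = 4, noise_rel = 0.01))
  expect_identical(generate_counts(9), generate_counts(9))
  rs <- reactor_scenario()
  cfg <- ftr_config()
  expect_identical(generate_reactor(rs, cfg, 2), generate_reactor(rs, cfg, 2))
})

test_that("survey generator spans the programmed saturation range", {
  sc <- survey_scenario(n_sites = 12, replicate_cv = 0.08)
  sv <- generate_survey(sc, seed = 13)
  sat <- percent_saturation(sv$ch4_nM * 1e-9, sv$temp_C, sv$salinity,
                            atm = sc$atm)
  by_site <- tapply(sat$saturation_pct, sv$site, mean)
  # site means recover the programmed endpoints within replicate noise
  # (CV 8% over 3 replicates -> sd of the site mean ~ 4.6%)
  expect_equal(min(by_site), 380, tolerance = 0.2)
  expect_equal(max(by_site), 189000, tolerance = 0.2)
  # each replicate's pipeline saturation matches its programmed truth
  expect_true(all(sat$saturation_pct > 0))
  expect_gt(max(sat$saturation_pct) / min(sat$saturation_pct), 100)
})

test_that("radon is uncorrelated with methane under the no-groundwater regime", {
  ok <- vapply(seq_len(200), function(s) {
    sv <- generate_survey(survey_scenario(n_sites = 50, n_replicates = 1,
                                          radon_regime = "no-groundwater"),
                          seed = s)
    abs(ch4_radon_correlation(sv$ch4_nM, sv$radon_Bq_m3)$r) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # the groundwater regime, by contrast, couples them
  svg <- generate_survey(survey_scenario(n_sites = 50, n_replicates = 1,
                                         radon_regime = "groundwater"),
                         seed = 1)
  expect_gt(ch4_radon_correlation(svg$ch4_nM, svg$radon_Bq_m3)$r, 0.5)
})

test_that("reactor generator is consistent with the plug-flow balance", {
  cfg <- ftr_config()
  zero <- reactor_scenario(max_rate_umol_cm3_h = 1e-12, noise_cv = 0)
  sim0 <- generate_reactor(zero, cfg, seed = 1)
  expect_equal(sim0$ch4$c_out_uM, rep(zero$c_in_ch4_uM, nrow(sim0$ch4)),
               tolerance = 1e-6)
  # oxygen pulses: rates drop to ~0 during the pulse, recover after the lag
  pulses <- data.frame(start_h = 30, end_h = 32, recovery_h = 2)
  scen <- reactor_scenario(noise_cv = 0, o2_pulses = pulses)
  sim <- generate_reactor(scen, cfg, seed = 1, times_h = seq(0, 48, by = 1))
  r <- volumetric_rate(sim$ch4, cfg)
  expect_equal(r$rate_umol_cm3_h[r$time_h %in% 30:32], rep(0, 3))
  post <- r$rate_umol_cm3_h[r$time_h == 35]
  pre <- r$rate_umol_cm3_h[r$time_h == 29]
  expect_gt(post, 0.9 * pre)
})

test_that("generated tables round-trip through the CSV layer unchanged", {
  sv <- generate_survey(survey_scenario(), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_units_csv(sv, path, units = c(temp_C = "degC", ch4_nM = "nmol/L",
                                      radon_Bq_m3 = "Bq/m3"))
  back <- read_units_csv(path, required = names(sv),
                         numeric_cols = c("temp_C", "salinity", "ch4_nM"))
  expect_equal(back$ch4_nM, sv$ch4_nM, tolerance = 1e-12)
  expect_equal(attr(back, "units")[["temp_C"]], "degC")
  # the round-tripped table drives the analysis without manual edits
  pip <- run_survey_pipeline(back, generate_wind(2))
  expect_equal(nrow(pip$bounds), 3)
  unlink(path)
})
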