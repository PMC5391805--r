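test_that("weather validation names the offending row or date", {
  w <- constant_weather(10)
  expect_silent(validate_weather(w))
  w_gap <- w[-5, ]
  expect_error(validate_weather(w_gap), format(w$date[5]))
  w_bad <- w
  w_bad$tmax[3] <- w_bad$tmin[3] - 1
  expect_error(validate_weather(w_bad), "tmax < tmin")
  w_neg <- w
  w_neg$srad[2] <- -1
  expect_error(validate_weather(w_neg), "radiation")
})

test_that("type constructors enforce their invariants", {
  expect_error(soil_profile(thickness = 0.1), "2 layers")
  expect_error(soil_profile(wcwp = 0.4, wcfc = 0.3), "wcwp")
  expect_error(cultivar_params(dtf = 12))
  expect_error(cultivar_params(tbase = 30, topt = 20))
  expect_error(cultivar_params(nonsense = 1), "unknown")
  expect_error(management_schedule(irrigation = list(rule = "sprinkle")))
  cv <- cultivar_params(dtf = 7)
  expect_equal(cv$dtf, 7)
})

test_that("AWD irrigation fires only at or above its suction threshold", {
  p <- two_layer_profile(theta = 0.45) # wet: suction below 20 kPa
  sched <- management_schedule(
    irrigation = list(rule = "awd", threshold_kpa = 20, sense_depth = 0.18,
                      dose = 50, start_dae = 15))
  expect_lt(sense_potential(p, 0.18, 0), 20)
  mg_wet <- apply_management(30, 0.5, sched, p, standing_water = 0)
  expect_equal(mg_wet$irrigation, 0)

  p_dry <- two_layer_profile(theta = 0.33) # drier than the threshold content
  expect_gt(sense_potential(p_dry, 0.18, 0), 20)
  mg_dry <- apply_management(30, 0.5, sched, p_dry, standing_water = 0)
  expect_equal(mg_dry$irrigation, 50)

  # standing water means zero suction: no event
  mg_pond <- apply_management(30, 0.5, sched, p_dry, standing_water = 10)
  expect_equal(mg_pond$irrigation, 0)
})

test_that("fertilizer events land in the surface mineral pools on their day", {
  p <- two_layer_profile()
  sched <- management_schedule(
    irrigation = list(rule = "none"),
    n_events = data.frame(dae = c(54, 60), amount = c(60, 30),
                          form = c("urea", "nh4")))
  mg <- apply_management(54, 0.8, sched, p, 0)
  expect_equal(mg$profile$urea_n[1], p$urea_n[1] + 60)
  expect_equal(mg$n_applied, 60)
  mg2 <- apply_management(60, 0.8, sched, p, 0)
  expect_equal(mg2$profile$nh4_n[1], p$nh4_n[1] + 30)
  mg3 <- apply_management(55, 0.8, sched, p, 0) # no-op day
  expect_equal(mg3$n_applied, 0)
  expect_equal(mg3$irrigation, 0)
})

test_that("a season run is bit-reproducible under a fixed seed", {
  cfg <- gen_scenarios("WME", seed = 5, days = 60)$AWD40
  r1 <- run_season(cfg)
  r2 <- run_season(cfg)
  expect_identical(r1$daily, r2$daily)
})

test_that("without radiation there is no growth", {
  w <- constant_weather(40, srad = 0)
  cfg <- sim_config(w, default_soil("lowland"), cultivar_params(),
                    management_schedule())
  r <- run_season(cfg)
  expect_true(all(diff(r$daily$wagt) <= 1e-9))
  expect_equal(r$daily$wagt[1], r$daily$wagt[nrow(r$daily)], tolerance = 1e-9)
})

test_that("the WAGT identity holds on every simulated day", {
  cfg <- gen_scenarios("WME", seed = 2, days = 80)$CF
  d <- run_season(cfg)$daily
  expect_equal(d$wagt, d$wlvg + d$wlvd + d$wst + d$wso, tolerance = 1e-9)
  expect_true(all(d$sw >= 0 & d$sw <= 1))
  expect_true(all(d$sn >= 0 & d$sn <= 1))
  expect_true(all(d$root_depth <= cfg$cultivar$d_max + 1e-12))
})

test_that("production levels gate the stress pathways selectively", {
  cfg <- gen_scenarios("MVD", seed = 6, days = 110)$V2D # drought, low DTF
  act <- run_season(cfg)
  pot <- run_season(cfg, production = "potential")
  wl <- run_season(cfg, production = "water_limited")
  expect_gte(pot$final$wagt, wl$final$wagt)
  expect_gte(wl$final$wagt, act$final$wagt - 1e-9)
  # indices are still reported in potential mode
  expect_true(any(wl$daily$sw < 1))
})
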