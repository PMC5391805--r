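test_that("weather generation is seed-pure and hits its targets", {
  w1 <- gen_weather(150, seed = 11)
  w2 <- gen_weather(150, seed = 11)
  expect_identical(w1, w2)
  expect_false(identical(w1, gen_weather(150, seed = 12)))
  validate_weather(w1) # satisfies all weather invariants

  # no rain requested: all dry
  wd <- gen_weather(120, list(rain_total = 0), seed = 5)
  expect_true(all(wd$rain == 0))

  # seasonal rain target recovered within 10% across many seeds
  totals <- vapply(1:50, function(s) {
    sum(gen_weather(120, list(rain_total = 600), seed = s)$rain)
  }, 0)
  expect_true(all(abs(totals - 600) / 600 < 0.10))

  # radiation is lower on wet days (cloud anticorrelation)
  w <- gen_weather(200, list(wet_day_prob = 0.5), seed = 2)
  expect_lt(mean(w$srad[w$rain > 0]), mean(w$srad[w$rain == 0]))
})

test_that("the WME family carries the AWD threshold ladder", {
  sc <- gen_scenarios("WME", seed = 3)
  expect_setequal(names(sc), c("CF", "AWD20", "AWD40", "AWD70"))
  thr <- vapply(sc[c("AWD20", "AWD40", "AWD70")],
                function(cfg) cfg$management$irrigation$threshold_kpa, 0)
  expect_equal(unname(thr), c(20, 40, 70))
  expect_equal(sc$AWD20$management$irrigation$dose, 50)
  expect_equal(sc$CF$management$irrigation$rule, "continuous_flooded")
})

test_that("the NFM family reproduces the sixteen split schedules", {
  sc <- gen_scenarios("NFM", seed = 3)
  expect_length(sc, 16)
  totals <- vapply(sc, function(cfg) sum(cfg$management$n_events$amount), 0)
  # includes true zero-N controls and the 225 kg treatment
  expect_true(any(totals == 0))
  expect_equal(unname(totals[["DSN4"]]), 225)
  expect_equal(sc$DSN4$management$n_events$dae, c(12, 34, 54, 76))
  expect_equal(sc$DSN4$management$n_events$amount, c(60, 60, 60, 45))
  expect_equal(unname(totals[["WSN1"]]), 30)
})

test_that("the ARE family is aerobic with 225 and 300 kg N", {
  sc <- gen_scenarios("ARE", seed = 3)
  totals <- sort(unique(vapply(sc, function(cfg)
    sum(cfg$management$n_events$amount), 0)))
  expect_equal(totals, c(225, 300))
  expect_equal(attr(sc$W1N1$profile, "bund"), 0)
})

test_that("the MVD family pairs irrigated and reproductive-stage drought", {
  sc <- gen_scenarios("MVD", seed = 3)
  expect_length(sc, 14) # 7 cultivar variants x 2 environments
  dtfs <- vapply(sc[grep("I$", names(sc))], function(cfg) cfg$cultivar$dtf, 0)
  expect_equal(min(dtfs), 1)
  expect_equal(max(dtfs), 10)
  drought <- sc$V1D$management$irrigation
  expect_equal(drought$rule, "rainfed_after")
  expect_equal(drought$dvs, 0.65) # irrigation withheld after panicle initiation
  expect_equal(sc$V1I$management$irrigation$rule, "continuous_flooded")
})

test_that("generated configurations satisfy the configuration invariants", {
  for (fam in c("WME", "ARE")) {
    for (cfg in gen_scenarios(fam, seed = 8)) {
      expect_s3_class(cfg, "sim_config")
      p <- cfg$profile
      expect_true(all(p$wcwp < p$wcfc & p$wcfc < p$wcst))
      expect_true(all(diff(p$z_mid) > 0))
    }
  }
  # generation is pure given the seed
  a <- gen_scenarios("MVD", seed = 4)
  b <- gen_scenarios("MVD", seed = 4)
  expect_identical(a, b)
})
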