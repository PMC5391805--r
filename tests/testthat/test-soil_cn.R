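test_that("rate modifiers hit their reference points", {
  m <- rate_modifiers(25, 0.38, 0.5, 0.38, 0.18)
  expect_equal(m$ft, 1)
  expect_equal(m$fw, 1)
  expect_equal(rate_modifiers(15, 0.38, 0.5, 0.38, 0.18)$ft, 0.5) # Q10 = 2
  expect_equal(rate_modifiers(25, 0.18, 0.5, 0.38, 0.18)$fw, 0)   # wilting point
  expect_lte(rate_modifiers(40, 0.38, 0.5, 0.38, 0.18)$ft, 1.2)   # capped
  # anaerobic decline toward saturation
  expect_lt(rate_modifiers(25, 0.5, 0.5, 0.38, 0.18)$fw, 1)
})

test_that("urea hydrolysis follows the exponential closed form", {
  hy <- hydrolyse_urea(one_layer(urea_n = 100), ft = 1)
  expect_equal(hy$layer$urea_n, 100 * exp(-0.25), tolerance = 1e-12)
  expect_equal(hy$layer$nh4_n, 100 * (1 - exp(-0.25)), tolerance = 1e-12)
  expect_equal(hy$layer$urea_n + hy$layer$nh4_n, 100) # N conserved
  hy0 <- hydrolyse_urea(one_layer(urea_n = 0), ft = 1)
  expect_equal(hy0$layer$nh4_n, 0)
})

test_that("decomposition balances carbon and mineralizes at the C:N rule", {
  # empty pools: nothing happens
  d0 <- decompose_om(one_layer(), ft = 1, fw = 1)
  expect_equal(d0$co2, 0)
  expect_equal(d0$n_min_net, 0)

  # fom at the microbial C:N with no humification: net N = decomposed C / 10
  ks <- default_constants()
  ks$humification <- 0
  lay <- one_layer(fom_c = 1000, fom_n = 100, nh4_n = 5)
  d <- decompose_om(lay, ft = 1, fw = 1, constants = ks)
  dec <- 1000 * (1 - exp(-ks$k_fom))
  expect_equal(d$n_min_net, dec / 10, tolerance = 1e-12)

  # carbon closure: d fom C + d hum C + CO2 = 0
  lay <- one_layer(fom_c = 2000, fom_n = 50, hum_c = 10000, hum_n = 1000,
                   nh4_n = 10, no3_n = 5)
  d <- decompose_om(lay, ft = 0.8, fw = 0.9)
  dc <- (d$layer$fom_c - lay$fom_c) + (d$layer$hum_c - lay$hum_c) + d$co2
  expect_equal(dc, 0, tolerance = 1e-10)
  # nitrogen closure within the layer
  n0 <- lay$fom_n + lay$hum_n + lay$nh4_n + lay$no3_n
  n1 <- d$layer$fom_n + d$layer$hum_n + d$layer$nh4_n + d$layer$no3_n
  expect_equal(n1, n0, tolerance = 1e-10)
})

test_that("immobilization is rationed by available mineral N", {
  # N-poor fresh material demands more N than the layer holds
  lay <- one_layer(fom_c = 5000, fom_n = 10, nh4_n = 0.01, no3_n = 0.01)
  d <- decompose_om(lay, ft = 1, fw = 1)
  expect_gte(d$layer$nh4_n, -1e-12)
  expect_gte(d$layer$no3_n, -1e-12)
})

test_that("nitrification and denitrification respect the aeration switch", {
  # at field capacity: no denitrification
  nd <- nitrify_denitrify(one_layer(nh4_n = 50, no3_n = 20, fom_c = 1000),
                          ft = 1, fw_nit = 1, theta = 0.38, wcst = 0.5,
                          wcfc = 0.38, ph = 6.5)
  expect_equal(nd$denitrified, 0)
  expect_gt(nd$nitrified, 0)

  # saturated: nitrification suppressed, denitrification active
  nd2 <- nitrify_denitrify(one_layer(nh4_n = 50, no3_n = 20, fom_c = 1000),
                           ft = 1, fw_nit = 0.3, theta = 0.5, wcst = 0.5,
                           wcfc = 0.38, ph = 6.5)
  expect_equal(nd2$nitrified, 0)
  expect_gt(nd2$denitrified, 0)

  # N closure: pool changes equal the gaseous loss
  lay <- one_layer(nh4_n = 30, no3_n = 15, fom_c = 800)
  nd3 <- nitrify_denitrify(lay, 1, 0.8, 0.45, 0.5, 0.38, 6.5)
  loss <- (lay$nh4_n + lay$no3_n) - (nd3$layer$nh4_n + nd3$layer$no3_n)
  expect_equal(loss, nd3$denitrified, tolerance = 1e-10)
})

test_that("volatilization follows the pH doubling rule with a 5.5 cutoff", {
  v <- volatilize(one_layer(nh4_n = 50), standing_water = 0, ph = 5.0,
                  temp = 25)
  expect_equal(v$nh3, 0)
  # instantaneous rates double per pH unit (small step isolates the rate)
  v7 <- volatilize(one_layer(nh4_n = 50), 0, ph = 7, temp = 25, dt = 1e-3)
  v8 <- volatilize(one_layer(nh4_n = 50), 0, ph = 8, temp = 25, dt = 1e-3)
  expect_equal(v8$nh3 / v7$nh3, 2, tolerance = 1e-3)
  v <- volatilize(one_layer(nh4_n = 1e-9), 100, ph = 8.5, temp = 35)
  expect_gte(v$layer$nh4_n, 0)
})

test_that("mineral N moves with water and NH4 is retarded", {
  p <- two_layer_profile(theta = 0.4)
  p$no3_n <- c(10, 0); p$nh4_n <- c(10, 0); p$urea_n <- c(10, 0)
  # zero flux: nothing moves
  tr0 <- transport_n(p, c(0, 0))
  expect_equal(tr0$profile$no3_n, p$no3_n)
  expect_equal(tr0$n_leach, 0)

  # downward flux equal to the layer water volume strips mobile species
  vol1 <- 0.4 * 0.1 * 1000
  tr <- transport_n(p, c(vol1, 0))
  expect_lt(tr$profile$no3_n[1], 1e-9)
  expect_equal(tr$profile$no3_n[2], 10, tolerance = 1e-9)
  expect_equal(tr$profile$urea_n[2], 10, tolerance = 1e-9)
  # NH4 moves 10x less
  expect_equal(tr$profile$nh4_n[2], 1, tolerance = 1e-9)
  # profile total conserved (no bottom flux)
  tot <- function(q) sum(q$no3_n + q$nh4_n + q$urea_n)
  expect_equal(tot(tr$profile), tot(p), tolerance = 1e-10)

  # bottom flux leaches
  tr2 <- transport_n(p, c(0, 5))
  expect_equal(tr2$n_leach, 0)
  p$no3_n <- c(0, 10)
  tr3 <- transport_n(p, c(0, 5))
  expect_gt(tr3$n_leach, 0)
  expect_equal(tot(tr3$profile) + tr3$n_leach, tot(p), tolerance = 1e-10)
})

test_that("atmospheric deposition applies the annual rate daily", {
  d <- deposit(one_layer(), rate = 10)
  expect_equal(d$deposited, 10 / 365, tolerance = 1e-12)
  expect_equal(d$layer$nh4_n, d$layer$no3_n) # 50:50 split
  expect_equal(deposit(one_layer(), rate = 0)$deposited, 0)
  # 365 daily applications recover the annual rate
  expect_equal(365 * d$deposited, 10, tolerance = 1e-10)
})
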