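test_that("thermal time accrues on the trapezoid between cardinal temperatures", {
  cv <- cultivar_params(tbase = 8, topt = 30, thigh = 42)
  expect_equal(advance_phenology(0, 8, cv)$tsum, 0)   # at base
  expect_equal(advance_phenology(0, 30, cv)$tsum, 22) # apex = topt - tbase
  expect_equal(advance_phenology(0, 42, cv)$tsum, 0)  # at upper limit
  expect_equal(advance_phenology(0, 36, cv)$tsum, 11) # halfway down
  # constant-topt weather flowers at tsum_fl / (topt - tbase) days
  days_to_fl <- ceiling(cv$tsum_fl / (cv$topt - cv$tbase))
  tsum <- 0; dvs <- 0; d <- 0
  while (dvs < 1) {
    ph <- advance_phenology(tsum, 30, cv)
    tsum <- ph$tsum; dvs <- ph$dvs; d <- d + 1
  }
  expect_equal(d, days_to_fl)
})

test_that("development stage is piecewise linear in thermal time", {
  cv <- cultivar_params(tsum_pi = 750, tsum_fl = 1200, tsum_mat = 1900)
  get_dvs <- function(tsum) advance_phenology(tsum, 8, cv)$dvs # no increment
  expect_equal(get_dvs(750), 0.65)
  expect_equal(get_dvs(1200), 1)
  expect_equal(get_dvs(1900), 2)
  expect_equal(get_dvs(375), 0.325)
})

test_that("daily growth is RUE on intercepted PAR, scaled by the worse stress", {
  cv <- cultivar_params(rue = 2.2, k_ext = 0.5)
  expect_equal(daily_growth(20, 0, cv), 0)      # no canopy
  expect_equal(daily_growth(20, 4, cv, 0, 1), 0) # full stress
  # frozen arithmetic: 2.2 * 0.5*20 * (1 - exp(-0.5*4)) * 10
  expect_equal(daily_growth(20, 4, cv), 2.2 * 0.5 * 20 * (1 - exp(-2)) * 10)
  expect_equal(daily_growth(20, 4, cv), 190.2263, tolerance = 1e-4)
})

test_that("allocation equals baseline tables without stress and shifts under it", {
  cv <- cultivar_params()
  # no stress, modest canopy: baseline tables exactly
  al <- allocate_biomass(100, dvs = 0.5, sw = 1, sn = 1, lai = 3, cultivar = cv)
  fs <- interp_table(cv$shoot_root_table, 0.5)
  expect_equal(al$root, 100 * (1 - fs))
  expect_equal(al$leaf, 100 * fs * 0.5)
  expect_equal(al$stem, 100 * fs * 0.5)
  expect_equal(al$panicle, 0)
  expect_equal(al$root + al$leaf + al$stem + al$panicle, 100,
               tolerance = 1e-12)

  # stress shifts assimilate root-ward
  al_s <- allocate_biomass(100, 0.5, sw = 0.5, sn = 1, lai = 3, cultivar = cv)
  expect_gt(al_s$root, al$root)
  expect_equal(al_s$root + al_s$leaf + al_s$stem + al_s$panicle, 100,
               tolerance = 1e-12)

  # after flowering under stress the panicle dominates the shoot
  al_f <- allocate_biomass(100, 1.2, sw = 0.6, sn = 0.8, lai = 5, cultivar = cv)
  expect_gte(al_f$panicle, al_f$stem)
  expect_gte(al_f$panicle, al_f$leaf)

  # crowded canopy shifts leaf share to stem and panicle
  al_c <- allocate_biomass(100, 0.75, 1, 1, lai = 7, cultivar = cv)
  al_o <- allocate_biomass(100, 0.75, 1, 1, lai = 5, cultivar = cv)
  expect_lt(al_c$leaf, al_o$leaf)
  expect_gt(al_c$stem + al_c$panicle, al_o$stem + al_o$panicle)

  # all increments non-negative over a stress/dvs sweep
  for (dvs in c(0, 0.4, 0.8, 1.1, 1.6, 2)) {
    for (s in c(0, 0.3, 0.7, 1)) {
      a <- allocate_biomass(50, dvs, s, 1, 4, cv)
      expect_true(all(unlist(a) >= 0))
      expect_equal(sum(unlist(a)), 50, tolerance = 1e-10)
    }
  }
})

test_that("canopy update grows LAI by SLA and kills leaves after flowering", {
  cv <- cultivar_params()
  crop <- list(dvs = 0.5, wlvg = 1000, wlvd = 0, lai = 3,
               leaf_n_mass = 45, wlvd_n = 0)
  # pre-flowering, no growth: unchanged
  c2 <- update_canopy(crop, 0, 1, 1, cv)
  expect_equal(c2$lai, 3)
  expect_equal(c2$wlvd, 0)

  # leaf increment converts by SLA
  c3 <- update_canopy(crop, 100, 1, 1, cv)
  sla <- interp_table(cv$sla_table, 0.5)
  expect_equal(c3$lai, 3 + 100 * sla / 1e4)

  # after flowering, unstressed: 1% of green leaf dies per day
  crop$dvs <- 1.5
  c4 <- update_canopy(crop, 0, 1, 1, cv)
  expect_equal(c4$wlvd, 10, tolerance = 1e-12)
  # stress doubles the death rate at s = 0
  c5 <- update_canopy(crop, 0, 0, 1, cv)
  expect_equal(c5$wlvd, 20, tolerance = 1e-12)
  # dead leaf N: half recycled, half to the dead pool; mass and N conserved
  expect_equal(c4$wlvg + c4$wlvd, 1000)
  expect_equal(c4$leaf_n_mass + c4$wlvd_n, 45, tolerance = 1e-12)
  expect_gt(c4$wlvd_n, 0)
})
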