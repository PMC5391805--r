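test_that("heat capacity mixes solid and water phases", {
  # H = 2.0e6 * BD/2.65 + 4.18e6 * theta
  expect_equal(heat_capacity(0, 1.325), 1.0e6)
  expect_equal(heat_capacity(0.3, 1.325), 1.0e6 + 4.18e6 * 0.3)
  th <- seq(0, 0.4, by = 0.05)
  expect_true(all(diff(heat_capacity(th, 1.325)) > 0))
  expect_error(heat_capacity(0.9, 1.325), "porosity")
})

test_that("thermal conductance rises with wetness and sand content", {
  expect_true(all(thermal_conductance(0.1, 0.6, 0.3) >
                    thermal_conductance(0.1, 0.6, 0.0)))
  # wet/dry ratio is substantial on a sandy soil
  ratio <- thermal_conductance(0.1, 0.6, 0.45) / thermal_conductance(0.1, 0.6, 0)
  expect_gt(ratio, 2)
  # sand-rich beats clay-rich at saturation
  expect_gt(thermal_conductance(0.1, 0.7, 0.45),
            thermal_conductance(0.7, 0.1, 0.45))
  expect_true(all(thermal_conductance(c(0.2, 0.5), c(0.3, 0.2), 0.25) > 0))
  expect_error(thermal_conductance(0.7, 0.5, 0.3), "exceed")
})

test_that("bare dry surface tracks daily mean air temperature", {
  sb <- surface_boundary(25, t0_prev = 18, standing_water = 0, residue = 0)
  expect_equal(sb$t0, 25)
})

test_that("standing water and residue damp the surface forcing", {
  run_t0 <- function(water, residue) {
    t0 <- 25
    out <- numeric(60)
    for (d in 1:60) {
      t_air <- 25 + 8 * sin(2 * pi * d / 10)
      sb <- surface_boundary(t_air, t0, water, residue)
      t0 <- sb$t0
      out[d] <- t0
    }
    out[21:60]
  }
  amp <- function(x) (max(x) - min(x)) / 2
  expect_lt(amp(run_t0(100, 0)), amp(run_t0(0, 0)))
  expect_lt(amp(run_t0(0, 5000)), amp(run_t0(0, 0)))
})

test_that("uniform profile at the boundary temperature is an equilibrium", {
  n <- 10
  st <- step_temperature(rep(25, n), z_mid = seq(0.05, by = 0.1, length.out = n),
                         thickness = rep(0.1, n), k = rep(1.5, n),
                         h = rep(2.5e6, n), t0 = 25, k0 = 1.5)
  expect_equal(st$temp, rep(25, n), tolerance = 1e-12)
  expect_equal(st$temp_mean, rep(25, n), tolerance = 1e-12)
})

test_that("a step change in the boundary diffuses monotonically to equilibrium", {
  n <- 10
  temp <- rep(25, n)
  prev <- temp
  for (d in 1:200) {
    st <- step_temperature(temp, seq(0.05, by = 0.1, length.out = n),
                           rep(0.1, n), rep(1.5, n), rep(2.5e6, n),
                           t0 = 35, k0 = 1.5, substeps = 4)
    temp <- st$temp
    expect_true(all(temp >= prev - 1e-12))
    prev <- temp
  }
  expect_equal(temp, rep(35, n), tolerance = 1e-3)
})

test_that("layer temperatures respect the maximum principle", {
  set.seed(42)
  n <- 8
  temp <- runif(n, 10, 30)
  lo <- min(temp); hi <- max(temp)
  for (d in 1:50) {
    t0 <- runif(1, 12, 28)
    lo <- min(lo, t0); hi <- max(hi, t0)
    st <- step_temperature(temp, seq(0.05, by = 0.1, length.out = n),
                           rep(0.1, n), rep(1.2, n), rep(2.2e6, n),
                           t0 = t0, k0 = 1.2, substeps = 6)
    temp <- st$temp
    expect_true(all(temp >= lo - 1e-9 & temp <= hi + 1e-9))
  }
})
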