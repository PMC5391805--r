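#' Volumetric heat capacity of a soil layer
#'
#' de Vries-style mixing of the solid and water phases:
#' `H = c_solid * (BD / 2.65) + c_water * theta`.
#'
#' @param theta volumetric water content, m3 m-3
#' @param bd bulk density, Mg m-3
#' @param constants list from [default_constants()]
#' @return volumetric heat capacity, J m-3 K-1
#' @export
heat_capacity <- function(theta, bd, constants = default_constants()) {
  porosity <- 1 - bd / 2.65
  if (any(theta < 0) || any(theta > porosity + 1e-12)) {
    stop("theta outside [0, porosity = 1 - BD/2.65]")
  }
  constants$c_solid * (bd / 2.65) + constants$c_water * theta
}

#' Thermal conductance of a soil layer
#'
#' Campbell-style empirical curve: conductivity rises monotonically from a dry
#' value to a texture-dependent saturated value as water content increases,
#' with sand-rich soils more conductive than clay-rich soils at saturation.
#'
#' @param clay,sand mass fractions, g g-1
#' @param theta volumetric water content, m3 m-3
#' @param constants list from [default_constants()]
#' @return thermal conductivity, J s-1 m-1 K-1 (W m-1 K-1)
#' @export
thermal_conductance <- function(clay, sand, theta, constants = default_constants()) {
  if (any(clay + sand > 1 + 1e-9)) stop("clay + sand must not exceed 1")
  tex <- ifelse(clay + sand > 0, sand / (clay + sand), 0.5)
  k_sat <- constants$k_sat_clay + (constants$k_sat_sand - constants$k_sat_clay) * tex
  # smooth saturating rise in theta; ~x4 between dry and theta = 0.45
  k <- constants$k_dry_base + (k_sat - constants$k_dry_base) * (1 - exp(-6 * theta))
  pmax(k, 1e-6)
}

#' Surface thermal boundary condition
#'
#' The surface driving temperature is a running mean of daily mean air
#' temperature whose responsiveness decreases with standing water depth and
#' residue mass (their heat buffering). With a bare, dry surface the boundary
#' equals the daily mean air temperature. The interface conductance and heat
#' capacity blend soil, ponded-water and residue properties.
#'
#' @param t_air daily mean air temperature, deg C
#' @param t0_prev previous day's surface boundary temperature, deg C
#' @param standing_water pond depth, mm
#' @param residue surface residue mass, kg ha-1
#' @param k_soil,h_soil conductance and heat capacity of the top soil layer
#' @param constants list from [default_constants()]
#' @return list with `t0`, `k0`, `h0`
#' @export
surface_boundary <- function(t_air, t0_prev, standing_water = 0, residue = 0,
                             k_soil = 1.5, h_soil = 2.5e6,
                             constants = default_constants()) {
  stopifnot(standing_water >= 0, residue >= 0)
  damp <- 1 / (1 + standing_water / constants$surf_damp_water +
                 residue / constants$surf_damp_residue)
  t0 <- t0_prev + damp * (t_air - t0_prev)
  # blend interface properties: water dominates when ponded, residue insulates
  w_frac <- standing_water / (standing_water + constants$surf_damp_water)
  r_frac <- residue / (residue + constants$surf_damp_residue)
  k0 <- (1 - r_frac) * ((1 - w_frac) * k_soil + w_frac * constants$k_water) +
    r_frac * 0.1 # residue mat is a poor conductor
  h0 <- (1 - w_frac) * h_soil + w_frac * constants$h_water
  list(t0 = t0, k0 = k0, h0 = h0)
}

#' Advance layer temperatures by heat conduction
#'
#' Solves the 1-D heat conduction (Fourier) equation on the layer grid with an
#' implicit (backward Euler) tridiagonal scheme: Dirichlet condition `t0` at
#' the surface, zero flux at the profile bottom. The day is divided into
#' `substeps` equal sub-steps; the reported daily temperature is the mean over
#' sub-steps.
#'
#' @param temp current layer temperatures, deg C
#' @param z_mid layer midpoint depths, m
#' @param thickness layer thicknesses, m
#' @param k layer thermal conductivities, W m-1 K-1
#' @param h layer volumetric heat capacities, J m-3 K-1
#' @param t0 surface boundary temperature, deg C
#' @param k0 surface interface conductivity, W m-1 K-1
#' @param dt total step length, s (default one day)
#' @param substeps number of implicit sub-steps
#' @return list with `temp` (end-of-step) and `temp_mean` (sub-step mean)
#' @export
step_temperature <- function(temp, z_mid, thickness, k, h, t0, k0,
                             dt = 86400, substeps = 24) {
  stopifnot(dt > 0, substeps >= 1, all(k > 0), all(h > 0))
  n <- length(temp)
  # interface conductances g[i]: between layer i and i+1; g0: surface-layer 1
  g0 <- k0 / z_mid[1]
  if (n > 1) {
    dz <- diff(z_mid)
    k_int <- 2 * k[-n] * k[-1] / (k[-n] + k[-1]) # harmonic mean
    g <- k_int / dz
  } else {
    g <- numeric(0)
  }
  cap <- h * thickness # J m-2 K-1
  dts <- dt / substeps
  acc <- numeric(n)
  for (s in seq_len(substeps)) {
    # tridiagonal system (cap/dts + G) T_new = cap/dts T_old + b
    lower <- c(if (n > 1) -g else numeric(0))
    upper <- lower
    diagm <- cap / dts + c(g0, rep(0, n - 1)) +
      c(g, 0) + c(0, g)
    rhs <- cap / dts * temp
    rhs[1] <- rhs[1] + g0 * t0
    temp <- solve_tridiag(lower, diagm, upper, rhs)
    acc <- acc + temp
  }
  list(temp = temp, temp_mean = acc / substeps)
}

## Thomas algorithm; lower/upper have length n-1
solve_tridiag <- function(lower, diagm, upper, rhs) {
  n <- length(diagm)
  if (n == 1) return(rhs / diagm)
  cp <- numeric(n - 1)
  dp <- numeric(n)
  cp[1] <- upper[1] / diagm[1]
  dp[1] <- rhs[1] / diagm[1]
  for (i in 2:n) {
    m <- diagm[i] - lower[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}
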