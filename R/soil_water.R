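#' Campbell retention parameters from a layer's pinned retention points
#'
#' Fits the two-parameter Campbell curve `psi = psi_e * (theta/WCST)^(-b)`
#' through the conventional anchor points (WCFC at 33 kPa, WCWP at 1500 kPa),
#' so the matric potential scale is consistent with the layer's own water
#' constants.
#'
#' @param wcst,wcfc,wcwp saturation, field capacity, wilting point, m3 m-3
#' @return list with `psi_e` (air entry, kPa) and `b_exp`
#' @export
retention_params <- function(wcst, wcfc, wcwp) {
  stopifnot(all(wcwp > 0), all(wcwp < wcfc), all(wcfc < wcst), all(wcst < 1))
  b <- log(1500 / 33) / log(wcfc / wcwp)
  psi_e <- 33 * (wcfc / wcst)^b
  list(psi_e = psi_e, b_exp = b)
}

#' Soil water content to matric potential (suction)
#'
#' @param theta volumetric water content, m3 m-3
#' @param wcst saturated water content
#' @param retention list from [retention_params()]
#' @return suction, kPa (positive; larger = drier)
#' @export
swc_to_potential <- function(theta, wcst, retention) {
  if (any(theta <= 0)) stop("theta must be positive")
  retention$psi_e * (theta / wcst)^(-retention$b_exp)
}

#' Matric potential to soil water content (inverse retention)
#'
#' @param psi suction, kPa
#' @inheritParams swc_to_potential
#' @return theta, m3 m-3
#' @export
potential_to_swc <- function(psi, wcst, retention) {
  stopifnot(all(psi > 0))
  wcst * (psi / retention$psi_e)^(-1 / retention$b_exp)
}

#' One daily step of the layered tipping-bucket water balance
#'
#' Order within the step: evaporation (pond first, then the surface layer,
#' limited to its extractable water); optional per-layer transpiration sinks;
#' infiltration of pond + incoming water filling layers to saturation
#' top-down; gravity drainage of water above field capacity cascading
#' downward; percolation out of the profile capped at `perc_cap`; surface
#' excess ponds up to the bund height, the rest runs off. Every transfer is
#' explicit, so mass closes identically.
#'
#' @param profile soil profile data frame (see [soil_profile()])
#' @param standing_water pond depth at start, mm
#' @param infil incoming surface water (rain + irrigation), mm
#' @param evap_pot potential soil/pond evaporation, mm
#' @param transp_sinks per-layer transpiration extraction, mm (already limited
#'   to extractable water by the caller, re-checked here)
#' @param perc_cap maximum percolation below the profile, mm d-1
#' @param bund bund height, mm
#' @param drain_frac fraction of above-field-capacity water draining per day
#' @return list: updated `profile`, `standing_water`, `evap` (actual),
#'   `transp` (actual), `percolation`, `runoff`, `flux_top` (mm entering layer
#'   1), `flux_down` (mm crossing the bottom of each layer), `shortfall`
#'   (unmet transpiration demand)
#' @export
step_water <- function(profile, standing_water, infil = 0, evap_pot = 0,
                       transp_sinks = NULL, perc_cap = 5, bund = 100,
                       drain_frac = NULL) {
  n <- length(profile$theta)
  if (is.null(drain_frac)) drain_frac <- attr(profile, "drain_frac") %||% 0.5
  th <- profile$theta
  vol <- function(i) th[i] * profile$thickness[i] * 1000 # mm
  cap_mm <- profile$thickness * 1000
  if (is.null(transp_sinks)) transp_sinks <- numeric(n)
  stopifnot(all(transp_sinks >= -1e-12), infil >= 0, evap_pot >= 0)
  flux_down <- numeric(n)

  ## evaporation: pond first, then surface layer down to wilting point
  e_pond <- min(evap_pot, standing_water)
  standing_water <- standing_water - e_pond
  e_soil_pot <- evap_pot - e_pond
  avail1 <- max(0, (th[1] - profile$wcwp[1])) * cap_mm[1]
  e_soil <- min(e_soil_pot, avail1)
  th[1] <- th[1] - e_soil / cap_mm[1]
  evap <- e_pond + e_soil

  ## transpiration sinks (per layer, limited to extractable water)
  avail <- pmax(0, (th - profile$wcwp)) * cap_mm
  taken <- pmin(pmax(transp_sinks, 0), avail)
  shortfall <- sum(transp_sinks) - sum(taken)
  th <- th - taken / cap_mm
  transp <- sum(taken)

  ## infiltration: pond + new water fills layers to saturation top-down
  surface_pool <- standing_water + infil
  inflow <- surface_pool
  flux_top <- 0
  for (i in seq_len(n)) {
    room <- max(0, (profile$wcst[i] - th[i])) * cap_mm[i]
    add <- min(inflow, room)
    th[i] <- th[i] + add / cap_mm[i]
    inflow <- inflow - add
    if (i == 1) flux_top <- add else flux_down[i - 1] <- flux_down[i - 1] + add
    if (inflow <= 0) break
  }
  infiltrated <- surface_pool - inflow
  surface_pool <- inflow # what would not fit in the profile

  ## gravity drainage: water above field capacity cascades downward
  perc <- 0
  for (i in seq_len(n)) {
    excess <- max(0, th[i] - profile$wcfc[i]) * cap_mm[i]
    flux <- drain_frac * excess
    if (i < n) {
      room <- max(0, (profile$wcst[i + 1] - th[i + 1])) * cap_mm[i + 1]
      flux <- min(flux, room)
      th[i + 1] <- th[i + 1] + flux / cap_mm[i + 1]
    } else {
      flux <- min(flux, perc_cap)
      perc <- perc + flux
    }
    th[i] <- th[i] - flux / cap_mm[i]
    flux_down[i] <- flux_down[i] + flux
  }

  ## ponded water seeps through a saturated profile (puddled percolation)
  if (surface_pool > 0 && perc < perc_cap) {
    sat <- all(th >= profile$wcst - 1e-12)
    if (sat) {
      seep <- min(surface_pool, perc_cap - perc)
      surface_pool <- surface_pool - seep
      perc <- perc + seep
      # passes along the whole profile
      flux_top <- flux_top + seep
      flux_down <- flux_down + seep
    }
  }

  ## pond up to bund height, excess runs off
  standing_water <- min(surface_pool, bund)
  runoff <- surface_pool - standing_water

  profile$theta <- th
  list(profile = profile, standing_water = standing_water, evap = evap,
       transp = transp, percolation = perc, runoff = runoff,
       flux_top = flux_top, flux_down = flux_down, shortfall = shortfall)
}
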