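#' Extractable water in a soil layer
#'
#' Available water is (theta - WCWP) x thickness. Extractable water equals the
#' maximum available water at saturation and declines toward a cultivar-scaled
#' fraction of the available water as the layer dries; the drought tolerance
#' factor (DTF, 1-10) sets that fraction:
#' `ew = available * (1/DTF + (1 - 1/DTF) * (theta - WCWP)/(WCST - WCWP))`.
#' With DTF = 1 extractable water equals available water at all contents.
#'
#' @param theta water content, m3 m-3
#' @param wcwp,wcst wilting point and saturation
#' @param thickness layer thickness, m
#' @param dtf drought tolerance factor (1-10)
#' @return extractable water, mm
#' @export
extractable_water <- function(theta, wcwp, wcst, thickness, dtf = 1) {
  if (any(theta < wcwp - 1e-12) || any(theta > wcst + 1e-12)) {
    stop("theta outside [WCWP, WCST]")
  }
  stopifnot(dtf >= 1, dtf <= 10)
  available <- (theta - wcwp) * thickness * 1000
  r <- 1 / dtf + (1 - 1 / dtf) * (theta - wcwp) / (wcst - wcwp)
  pmax(0, available * r)
}

#' Partition transpiration demand over rooted layers
#'
#' First-pass weights are the product of the layer's share of root mass and
#' its share of extractable water, normalized; uptake per layer is capped at
#' its extractable water, and one redistribution pass sends unmet demand to
#' layers with spare extractable water. Total uptake never exceeds
#' min(demand, total extractable water).
#'
#' @param t_pot potential transpiration, mm d-1
#' @param root_mass per-layer root dry matter, kg ha-1
#' @param ew per-layer extractable water, mm
#' @return list: `uptake` per layer (mm), `total` (mm)
#' @export
partition_uptake <- function(t_pot, root_mass, ew) {
  stopifnot(t_pot >= 0, length(root_mass) == length(ew))
  n <- length(ew)
  if (t_pot == 0 || sum(root_mass) <= 0 || sum(ew) <= 0) {
    return(list(uptake = numeric(n), total = 0))
  }
  w <- (root_mass / sum(root_mass)) * (ew / sum(ew))
  if (sum(w) <= 0) return(list(uptake = numeric(n), total = 0))
  w <- w / sum(w)
  uptake <- pmin(w * t_pot, ew)
  deficit <- t_pot - sum(uptake)
  if (deficit > 1e-15) {
    spare <- ew - uptake
    if (sum(spare) > 0) {
      extra <- pmin(deficit * spare / sum(spare), spare)
      uptake <- uptake + extra
    }
  }
  list(uptake = uptake, total = sum(uptake))
}

#' Drought stress index Sw
#'
#' With r = uptake / potential transpiration, the index is the normalized
#' exponential `Sw = (1 - exp(-a r)) / (1 - exp(-a))` with `a = DTF - 1`,
#' taking the analytic limit Sw = r as a -> 0 (DTF = 1, linear response). Sw
#' is 1 when there is no transpiration demand, and multiplies potential
#' photosynthesis downstream.
#'
#' @param total_uptake actual transpiration, mm d-1
#' @param t_pot potential transpiration, mm d-1
#' @param dtf drought tolerance factor (1-10)
#' @return Sw in 0..1
#' @export
drought_index <- function(total_uptake, t_pot, dtf = 1) {
  stopifnot(t_pot >= 0, dtf >= 1, dtf <= 10)
  if (t_pot == 0) return(1)
  r <- clamp(total_uptake / t_pot, 0, 1)
  a <- dtf - 1
  if (a < 1e-9) return(r)
  (1 - exp(-a * r)) / (1 - exp(-a))
}
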