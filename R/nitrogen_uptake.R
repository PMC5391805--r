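#' Daily crop nitrogen demand
#'
#' Demand is the sum over organs of (critical N mass - actual N mass), floored
#' at zero per organ and capped by the cultivar's maximum daily uptake. The
#' leaf critical mass is `n_crit_leaf x LAI x 10` (g N m-2 leaf to kg N
#' ha-1); stem and panicle critical masses use development-dependent critical
#' concentrations; roots use the optimal root C:N ratio.
#'
#' @param crop crop state list (see [run_season()] internals): needs lai,
#'   wst, wso, leaf_n_mass, stem_n, pan_n, dvs
#' @param root_mass,root_n totals over the profile, kg ha-1
#' @param cultivar list from [cultivar_params()]
#' @param constants list from [default_constants()]
#' @return list: `demand` (kg N ha-1 d-1, capped), `deficits` named vector of
#'   per-organ deficits (uncapped)
#' @export
n_demand <- function(crop, root_mass, root_n, cultivar,
                     constants = default_constants()) {
  leaf_crit <- cultivar$n_crit_leaf * crop$lai * 10
  stem_crit <- interp_table(cultivar$n_crit_stem_table, crop$dvs) * crop$wst
  pan_crit <- cultivar$n_crit_panicle * crop$wso
  root_crit <- constants$root_c_frac / cultivar$root_cn_opt * root_mass
  deficits <- c(
    leaf = max(0, leaf_crit - crop$leaf_n_mass),
    stem = max(0, stem_crit - crop$stem_n),
    panicle = max(0, pan_crit - crop$pan_n),
    root = max(0, root_crit - root_n)
  )
  list(demand = min(sum(deficits), cultivar$n_max_uptake), deficits = deficits)
}

#' Mass-flow nitrogen uptake
#'
#' N carried into the roots with the transpiration stream: per layer, water
#' uptake times the dissolved mineral N concentration (pool / layer water
#' volume), capped at the pool. Wetter soil dilutes the concentration and
#' reduces mass-flow uptake per mm of water taken.
#'
#' @param water_uptake per-layer water uptake, mm
#' @param mineral_n per-layer plant-available mineral N (NH4 + NO3), kg ha-1
#' @param water_volume per-layer water volume, mm
#' @return per-layer uptake, kg N ha-1 d-1
#' @export
mass_flow_uptake <- function(water_uptake, mineral_n, water_volume) {
  stopifnot(all(water_uptake >= -1e-12))
  conc <- ifelse(water_volume > 0, mineral_n / water_volume, 0)
  pmin(water_uptake * conc, mineral_n)
}

#' Diffusive nitrogen uptake
#'
#' Fills the demand left after mass flow. The per-layer capacity is
#' `d_coef x (root share) x fW(theta) x mineral N`; the remaining demand is
#' distributed over layers proportionally to capacity and capped by it and by
#' the remaining pool.
#'
#' @param remaining_demand kg N ha-1 d-1 still unmet after mass flow
#' @param mineral_n per-layer mineral N remaining, kg ha-1
#' @param root_mass per-layer root dry matter, kg ha-1
#' @param fw per-layer moisture factor in 0..1 (wetness ramp)
#' @param constants list from [default_constants()]
#' @return per-layer uptake, kg N ha-1 d-1
#' @export
diffusion_uptake <- function(remaining_demand, mineral_n, root_mass, fw,
                             constants = default_constants()) {
  stopifnot(remaining_demand >= 0)
  n <- length(mineral_n)
  if (remaining_demand == 0 || sum(root_mass) <= 0) return(numeric(n))
  cap <- constants$d_coef * (root_mass / sum(root_mass)) * fw * mineral_n
  cap <- pmin(cap, mineral_n)
  if (sum(cap) <= 0) return(numeric(n))
  take <- min(remaining_demand, sum(cap))
  take * cap / sum(cap)
}

#' Nitrogen deficiency stress index SN
#'
#' The ratio of actual N uptake to N demand, clipped to 0..1; SN = 1 when
#' demand is zero. The growth reduction applied downstream is the greater of
#' the two stresses, i.e. `min(Sw, SN)`.
#'
#' @param actual_uptake kg N ha-1 d-1
#' @param demand kg N ha-1 d-1
#' @return SN in 0..1
#' @export
n_stress_index <- function(actual_uptake, demand) {
  stopifnot(demand >= 0)
  if (demand == 0) return(1)
  clamp(actual_uptake / demand, 0, 1)
}
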