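#' Advance phenology by one day
#'
#' Daily effective thermal time is a trapezoidal response of the mean air
#' temperature between the cultivar's cardinal temperatures (zero at/below
#' tbase and at/above thigh, maximum `topt - tbase` at topt). Development
#' stage is piecewise linear in accumulated thermal time: 0.65 at panicle
#' initiation, 1.0 at flowering, 2.0 at maturity.
#'
#' @param tsum accumulated thermal time, deg C d
#' @param tmean daily mean air temperature, deg C
#' @param cultivar list from [cultivar_params()]
#' @return list: `tsum`, `dvs`
#' @export
advance_phenology <- function(tsum, tmean, cultivar) {
  stopifnot(cultivar$tbase < cultivar$topt, cultivar$topt < cultivar$thigh)
  tsum <- tsum + thermal_factor(tmean, cultivar$tbase, cultivar$topt, cultivar$thigh)
  list(tsum = tsum, dvs = dvs_from_tsum(tsum, cultivar))
}

dvs_from_tsum <- function(tsum, cultivar) {
  pi_ <- cultivar$tsum_pi; fl <- cultivar$tsum_fl; mat <- cultivar$tsum_mat
  ifelse(tsum <= pi_, 0.65 * tsum / pi_,
         ifelse(tsum <= fl, 0.65 + 0.35 * (tsum - pi_) / (fl - pi_),
                pmin(2, 1 + (tsum - fl) / (mat - fl))))
}

#' Stress-limited daily biomass production
#'
#' Radiation-use-efficiency model on intercepted photosynthetically active
#' radiation: `potential = rue x 0.5 srad x (1 - exp(-k LAI)) x 10`
#' (g m-2 to kg ha-1); the actual growth is the potential scaled by the
#' greater of the drought and nitrogen stresses, `min(Sw, SN)`.
#'
#' @param srad shortwave radiation, MJ m-2 d-1
#' @param lai leaf area index
#' @param cultivar list from [cultivar_params()]
#' @param sw,sn stress indices in 0..1
#' @return gross new biomass, kg DM ha-1 d-1
#' @export
daily_growth <- function(srad, lai, cultivar, sw = 1, sn = 1) {
  stopifnot(srad >= 0, lai >= 0)
  pot <- cultivar$rue * 0.5 * srad * (1 - exp(-cultivar$k_ext * lai)) * 10
  pot * min(sw, sn)
}

#' Stress-modified assimilate allocation
#'
#' Baseline shoot fraction and within-shoot organ fractions come from the
#' cultivar's development-stage tables. Under stress (s = min(Sw, SN) < 1)
#' the shoot fraction is multiplied by `0.5 + 0.5 s` (assimilate shifts to
#' the roots), and the stem's share is multiplied by s with the freed share
#' split leaf:panicle = 1:2 before flowering and given entirely to the
#' panicle after. Above LAI 6, 10% of the leaf share moves to stem and
#' panicle (light competition). After flowering the panicle receives the
#' largest within-shoot share (storage priority) by construction of the
#' tables plus the stress shift. Fractions are renormalized to sum to one.
#'
#' @param new_biomass kg DM ha-1 to allocate
#' @param dvs development stage
#' @param sw,sn stress indices
#' @param lai current leaf area index
#' @param cultivar list from [cultivar_params()]
#' @param constants list from [default_constants()]
#' @return list of increments: `root`, `leaf`, `stem`, `panicle` (kg ha-1)
#' @export
allocate_biomass <- function(new_biomass, dvs, sw = 1, sn = 1, lai = 0,
                             cultivar, constants = default_constants()) {
  stopifnot(new_biomass >= 0)
  s <- min(sw, sn)
  fs <- interp_table(cultivar$shoot_root_table, dvs)
  fs <- fs * (constants$root_shift_floor + (1 - constants$root_shift_floor) * s)
  fl <- interp_table(cultivar$partition_leaf_table, dvs)
  fst <- interp_table(cultivar$partition_stem_table, dvs)
  fso <- interp_table(cultivar$partition_panicle_table, dvs)
  tot <- fl + fst + fso
  fl <- fl / tot; fst <- fst / tot; fso <- fso / tot
  ## stress: stem share reduced, freed share to leaf:panicle 1:2 (0:1 after
  ## flowering)
  freed <- fst * (1 - s)
  fst <- fst * s
  if (dvs < 1) {
    fl <- fl + freed / 3
    fso <- fso + 2 * freed / 3
  } else {
    fso <- fso + freed
  }
  ## light competition: crowded canopy shifts leaf share to stem + panicle
  if (lai > constants$lai_crowd) {
    shift <- constants$crowd_shift * fl
    fl <- fl - shift
    fst <- fst + shift / 2
    fso <- fso + shift / 2
  }
  shoot <- new_biomass * fs
  list(root = new_biomass * (1 - fs),
       leaf = shoot * fl, stem = shoot * fst, panicle = shoot * fso)
}

#' Update leaf area and leaf death
#'
#' New leaf area is the leaf increment times the development-dependent
#' specific leaf area. A background relative leaf death rate acts after
#' flowering, increased under stress (`0.01 x (2 - min(Sw, SN)) d-1`);
#' dead leaf mass moves from WLVG to WLVD and carries its N, of which half is
#' recycled to the remaining green leaves.
#'
#' @param crop crop state list (wlvg, wlvd, lai, leaf_n_mass, wlvd_n, dvs)
#' @param leaf_inc new green leaf mass, kg ha-1
#' @param sw,sn stress indices
#' @param cultivar list from [cultivar_params()]
#' @param constants list from [default_constants()]
#' @return updated crop state list
#' @export
update_canopy <- function(crop, leaf_inc, sw = 1, sn = 1, cultivar,
                          constants = default_constants()) {
  sla <- interp_table(cultivar$sla_table, crop$dvs) # m2 kg-1
  crop$wlvg <- crop$wlvg + leaf_inc
  crop$lai <- crop$lai + leaf_inc * sla / 1e4
  if (crop$dvs > 1 && crop$wlvg > 0) {
    s <- min(sw, sn)
    rate <- constants$leaf_death_base * (2 - s)
    dead <- rate * crop$wlvg
    n_conc <- if (crop$wlvg > 0) crop$leaf_n_mass / crop$wlvg else 0
    dead_n <- dead * n_conc
    sla_now <- if (crop$wlvg > 0) crop$lai * 1e4 / crop$wlvg else sla
    crop$wlvg <- crop$wlvg - dead
    crop$wlvd <- crop$wlvd + dead
    crop$lai <- max(0, crop$lai - dead * sla_now / 1e4)
    crop$leaf_n_mass <- crop$leaf_n_mass - dead_n +
      constants$leaf_n_recycle * dead_n
    crop$wlvd_n <- crop$wlvd_n + (1 - constants$leaf_n_recycle) * dead_n
  }
  crop
}
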