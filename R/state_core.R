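#' Cultivar parameter set
#'
#' Genetic parameters of a rice cultivar: maximum rooting depth, drought
#' tolerance factor (DTF, 1 = drought sensitive with a linear photosynthesis
#' response to drying, 10 = tolerant), cardinal temperatures and thermal-time
#' thresholds for phenology, radiation-use efficiency, canopy extinction,
#' specific-leaf-area and assimilate-partitioning tables against development
#' stage, optimal root C:N, and nitrogen uptake/critical-content parameters.
#' Any default can be overridden by name.
#'
#' @param ... named overrides of the defaults listed in the source.
#' @return object of class `cultivar_params`
#' @export
cultivar_params <- function(...) {
  p <- list(
    d_max = 0.6,           # maximum rooting depth, m
    dtf = 2,               # drought tolerance factor, 1-10
    tbase = 8, topt = 30, thigh = 42,  # cardinal temperatures, deg C
    tsum_pi = 750, tsum_fl = 1200, tsum_mat = 1900, # thermal time, deg C d
    rue = 2.5,             # g DM MJ-1 intercepted PAR
    k_ext = 0.5,           # canopy extinction coefficient
    sla_table = cbind(dvs = c(0, 1, 2), sla = c(30, 20, 17)), # m2 kg-1
    partition_leaf_table = cbind(dvs = c(0, 0.5, 0.75, 1, 1.2, 2),
                                 frac = c(0.55, 0.50, 0.35, 0.10, 0, 0)),
    partition_stem_table = cbind(dvs = c(0, 0.5, 0.75, 1, 1.2, 2),
                                 frac = c(0.45, 0.50, 0.55, 0.40, 0, 0)),
    partition_panicle_table = cbind(dvs = c(0, 0.5, 0.75, 1, 1.2, 2),
                                    frac = c(0, 0, 0.10, 0.50, 1, 1)),
    shoot_root_table = cbind(dvs = c(0, 0.5, 1, 2),
                             frac = c(0.5, 0.75, 0.95, 0.95)),
    root_cn_opt = 25,      # optimal root C:N ratio
    n_max_uptake = 8,      # kg N ha-1 d-1
    n_crit_leaf = 1.5,     # g N m-2 leaf
    n_min_leaf = 0.5,      # g N m-2 leaf
    n_crit_stem_table = cbind(dvs = c(0, 1, 2),
                              conc = c(0.015, 0.010, 0.005)), # kg N kg-1 DM
    n_crit_panicle = 0.010 # kg N kg-1 DM
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown cultivar parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$dtf >= 1, p$dtf <= 10, p$d_max > 0,
            p$tbase < p$topt, p$topt < p$thigh)
  psum <- interp_table(p$partition_leaf_table, c(0, 0.5, 1, 1.5, 2)) +
    interp_table(p$partition_stem_table, c(0, 0.5, 1, 1.5, 2)) +
    interp_table(p$partition_panicle_table, c(0, 0.5, 1, 1.5, 2))
  if (any(abs(psum - 1) > 1e-8)) stop("partition fractions must sum to 1")
  structure(p, class = "cultivar_params")
}

#' Layered soil profile
#'
#' Builds the per-layer state table (texture, bulk density, pH, retention
#' points, water content, temperature, organic and mineral C/N pools, root
#' mass) plus profile-level attributes: standing water, surface residue,
#' drainage parameters and bund height.
#'
#' @param thickness layer thicknesses, m (>= 2 layers)
#' @param clay,sand mass fractions (recycled)
#' @param bd bulk density, Mg m-3
#' @param ph soil pH
#' @param wcst,wcfc,wcwp retention points, m3 m-3
#' @param theta initial water content (default field capacity)
#' @param temp initial temperature, deg C
#' @param fom_c,fom_n,hum_c,hum_n organic pools, kg ha-1 per layer
#' @param urea_n,nh4_n,no3_n mineral pools, kg ha-1 per layer
#' @param standing_water initial pond, mm
#' @param residue_mass,residue_cn surface residue, kg ha-1, and its C:N
#' @param drain_frac fraction of above-field-capacity water draining per day
#' @param perc_cap max percolation below the profile, mm d-1
#' @param bund bund height, mm
#' @return data frame of class `soil_profile` with one row per layer
#' @export
soil_profile <- function(thickness = rep(0.1, 9), clay = 0.35, sand = 0.25,
                         bd = 1.3, ph = 6.5, wcst = 0.50, wcfc = 0.38,
                         wcwp = 0.18, theta = wcfc, temp = 25,
                         fom_c = 500, fom_n = 20,
                         hum_c = 13000 * exp(-2 * (cumsum(thickness) - thickness / 2)),
                         hum_n = hum_c / 10,
                         urea_n = 0, nh4_n = 5, no3_n = 2,
                         standing_water = 0, residue_mass = 0, residue_cn = 40,
                         drain_frac = 0.5, perc_cap = 5, bund = 100) {
  n <- length(thickness)
  if (n < 2) stop("a soil profile needs at least 2 layers")
  prof <- data.frame(
    thickness = thickness,
    z_mid = cumsum(thickness) - thickness / 2,
    clay = rep_len(clay, n), sand = rep_len(sand, n),
    bd = rep_len(bd, n), ph = rep_len(ph, n),
    wcst = rep_len(wcst, n), wcfc = rep_len(wcfc, n), wcwp = rep_len(wcwp, n),
    theta = rep_len(theta, n), temp = rep_len(temp, n),
    fom_c = rep_len(fom_c, n), fom_n = rep_len(fom_n, n),
    hum_c = rep_len(hum_c, n), hum_n = rep_len(hum_n, n),
    urea_n = rep_len(urea_n, n), nh4_n = rep_len(nh4_n, n),
    no3_n = rep_len(no3_n, n),
    root_mass = 0, root_n = 0
  )
  stopifnot(all(prof$wcwp > 0), all(prof$wcwp < prof$wcfc),
            all(prof$wcfc < prof$wcst), all(prof$wcst < 1),
            all(prof$theta >= prof$wcwp - 1e-12),
            all(prof$theta <= prof$wcst + 1e-12),
            standing_water >= 0)
  attr(prof, "standing_water") <- standing_water
  attr(prof, "residue_mass") <- residue_mass
  attr(prof, "residue_cn") <- residue_cn
  attr(prof, "drain_frac") <- drain_frac
  attr(prof, "perc_cap") <- perc_cap
  attr(prof, "bund") <- bund
  class(prof) <- c("soil_profile", "data.frame")
  prof
}

#' Management schedule
#'
#' Establishment (method, density and initial seedling biomass — seedling
#' raising itself is not simulated, so initial biomass is an input),
#' irrigation rule, nitrogen split events, and residue incorporation.
#'
#' Irrigation rules: `list(rule = "continuous_flooded", target_depth = 50)`;
#' `list(rule = "awd", threshold_kpa, sense_depth, dose, start_dae = 15)`
#' (maintains a shallow flood before `start_dae`, then applies `dose` mm
#' whenever the sensed suction reaches the threshold);
#' `list(rule = "fixed_events", events = data.frame(dae, mm))`;
#' `list(rule = "rainfed_after", dvs = 0.65, target_depth = 50)` (flooded
#' until the crop reaches `dvs`, then rainfed);
#' `list(rule = "none")`.
#'
#' @param establishment list: method ("transplant" or "direct-seed"),
#'   density (hills m-2), init_wlvg, init_wst, init_root (kg ha-1)
#' @param irrigation irrigation rule list (see Details)
#' @param n_events data.frame with columns dae, amount (kg N ha-1), form
#'   ("urea" or "nh4")
#' @param residue_in list: mass (kg ha-1), cn
#' @return object of class `management_schedule`
#' @export
management_schedule <- function(
    establishment = list(method = "transplant", density = 25,
                         init_wlvg = 60, init_wst = 40, init_root = 30),
    irrigation = list(rule = "continuous_flooded", target_depth = 50),
    n_events = data.frame(dae = numeric(), amount = numeric(),
                          form = character()),
    residue_in = list(mass = 0, cn = 40)) {
  stopifnot(irrigation$rule %in% c("continuous_flooded", "awd", "fixed_events",
                                   "rainfed_after", "none"))
  if (nrow(n_events)) stopifnot(all(n_events$amount >= 0),
                                all(n_events$form %in% c("urea", "nh4")))
  if (irrigation$rule == "awd") {
    stopifnot(irrigation$threshold_kpa > 0, irrigation$dose >= 0)
    irrigation$start_dae <- irrigation$start_dae %||% 15
  }
  structure(list(establishment = establishment, irrigation = irrigation,
                 n_events = n_events, residue_in = residue_in),
            class = "management_schedule")
}

#' Simulation configuration
#'
#' Bundles weather, soil, cultivar and management with the random seed and
#' numerical settings. A fixed seed makes the whole run bit-reproducible.
#'
#' @param weather data frame: date, tmin, tmax, srad, rain
#' @param profile [soil_profile()]
#' @param cultivar [cultivar_params()]
#' @param management [management_schedule()]
#' @param seed integer seed for any stochastic components
#' @param substeps_heat sub-steps per day for heat conduction (>= 1)
#' @param constants process constants, see [default_constants()]
#' @return object of class `sim_config`
#' @export
sim_config <- function(weather, profile, cultivar = cultivar_params(),
                       management = management_schedule(), seed = 1L,
                       substeps_heat = 24L,
                       constants = default_constants()) {
  validate_weather(weather)
  stopifnot(inherits(profile, "soil_profile"),
            inherits(cultivar, "cultivar_params"),
            inherits(management, "management_schedule"),
            substeps_heat >= 1)
  structure(list(weather = weather, profile = profile, cultivar = cultivar,
                 management = management, seed = as.integer(seed),
                 substeps_heat = as.integer(substeps_heat),
                 constants = constants),
            class = "sim_config")
}

#' Validate a daily weather table
#'
#' Checks column presence, contiguous dates (a gap fails naming the missing
#' date), tmax >= tmin, and non-negative radiation and rain.
#'
#' @param weather data frame: date (Date), tmin, tmax, srad, rain
#' @return the weather table, invisibly
#' @export
validate_weather <- function(weather) {
  need <- c("date", "tmin", "tmax", "srad", "rain")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather table missing columns: ",
                         paste(miss, collapse = ", "))
  d <- as.Date(weather$date)
  if (anyNA(d)) stop("unparseable dates in weather table")
  if (anyDuplicated(d)) stop("duplicate weather date: ",
                             format(d[duplicated(d)][1]))
  gaps <- which(diff(d) != 1)
  if (length(gaps)) stop("weather gap: missing ", format(d[gaps[1]] + 1))
  bad <- which(weather$tmax < weather$tmin)
  if (length(bad)) stop("tmax < tmin on ", format(d[bad[1]]))
  if (any(weather$srad < 0)) stop("negative radiation in weather table")
  if (any(weather$rain < 0)) stop("negative rainfall in weather table")
  invisible(weather)
}

#' Apply one day's management
#'
#' Checks the irrigation rule (AWD fires only when the sensed suction reaches
#' its threshold; flood rules top the pond up to the target depth) and the
#' nitrogen split schedule (fertilizer N enters the surface layer's urea or
#' NH4 pool).
#'
#' @param dae days after emergence
#' @param dvs current development stage
#' @param schedule [management_schedule()]
#' @param profile soil profile data frame
#' @param standing_water current pond depth, mm
#' @return list: `profile`, `irrigation` (mm), `n_applied` (kg N ha-1)
#' @export
apply_management <- function(dae, dvs, schedule, profile, standing_water) {
  irr <- 0
  rule <- schedule$irrigation
  flood_top_up <- function(target) max(0, target - standing_water)
  if (rule$rule == "continuous_flooded") {
    irr <- flood_top_up(rule$target_depth %||% 50)
  } else if (rule$rule == "awd") {
    if (dae < rule$start_dae) {
      irr <- flood_top_up(20)
    } else if (standing_water <= 0) {
      psi <- sense_potential(profile, rule$sense_depth, standing_water)
      if (psi >= rule$threshold_kpa) irr <- rule$dose
    }
  } else if (rule$rule == "fixed_events") {
    ev <- rule$events
    irr <- sum(ev$mm[ev$dae == dae])
  } else if (rule$rule == "rainfed_after") {
    if (dvs < (rule$dvs %||% 0.65)) irr <- flood_top_up(rule$target_depth %||% 50)
  }
  n_applied <- 0
  ne <- schedule$n_events
  if (nrow(ne)) {
    today <- ne[ne$dae == dae, , drop = FALSE]
    for (i in seq_len(nrow(today))) {
      if (today$form[i] == "urea") {
        profile$urea_n[1] <- profile$urea_n[1] + today$amount[i]
      } else {
        profile$nh4_n[1] <- profile$nh4_n[1] + today$amount[i]
      }
      n_applied <- n_applied + today$amount[i]
    }
  }
  list(profile = profile, irrigation = irr, n_applied = n_applied)
}

#' Matric suction sensed at a given depth
#'
#' Zero (flooded) while standing water is present, otherwise the Campbell
#' suction of the layer containing the sensing depth.
#'
#' @param profile soil profile data frame
#' @param depth sensing depth, m
#' @param standing_water pond depth, mm
#' @return suction, kPa
#' @export
sense_potential <- function(profile, depth, standing_water = 0) {
  if (standing_water > 0) return(0)
  z_bot <- cumsum(profile$thickness)
  i <- which(z_bot >= depth - 1e-9)[1]
  if (is.na(i)) i <- nrow(profile)
  ret <- retention_params(profile$wcst[i], profile$wcfc[i], profile$wcwp[i])
  swc_to_potential(max(profile$theta[i], 1e-6), profile$wcst[i], ret)
}
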