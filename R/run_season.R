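#' Run one cropping season
#'
#' The daily driver loop. Step order within each day: weather, potential ET
#' (Priestley-Taylor, partitioned by Beer's law), soil temperature (implicit
#' heat conduction), soil C/N transformation, crop N demand, water uptake and
#' the drought index Sw, N uptake and the nitrogen index SN, photosynthesis
#' and stress-modified allocation, root growth and senescence, water
#' redistribution and N transport, then management events. Water and nitrogen
#' balances are audited every day; the residuals are reported in the output
#' table and must stay at rounding error.
#'
#' The run starts at the establishment date (the first weather row) with the
#' seedling biomass given in the management schedule, and ends at maturity
#' (DVS = 2) or when the weather table is exhausted.
#'
#' `production` selects the standard production levels of crop simulation:
#' `"actual"` applies both stresses; `"potential"` holds Sw and SN at 1 in
#' the growth and allocation pathways; `"water_limited"` applies only Sw
#' (nitrogen non-limiting); `"n_limited"` applies only SN. Soil processes
#' and uptake run identically in every mode, so the indices are always
#' reported.
#'
#' @param cfg a [sim_config()]
#' @param production one of "actual", "potential", "water_limited",
#'   "n_limited"
#' @param disable_stress shorthand for `production = "potential"`
#' @return object of class `paddy_season`: list with `daily` (one row per
#'   day), `final` (end-of-season summary incl. `yield` at 14% moisture),
#'   and `config`
#' @export
run_season <- function(cfg, production = c("actual", "potential",
                                           "water_limited", "n_limited"),
                       disable_stress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  production <- match.arg(production)
  if (disable_stress) production <- "potential"
  use_sw <- production %in% c("actual", "water_limited")
  use_sn <- production %in% c("actual", "n_limited")
  set.seed(cfg$seed)
  ks <- cfg$constants
  wtr <- cfg$weather
  wtr$date <- as.Date(wtr$date)
  cult <- cfg$cultivar
  mgmt <- cfg$management
  prof_df <- cfg$profile
  nl <- nrow(prof_df)
  standing <- attr(prof_df, "standing_water")
  residue <- attr(prof_df, "residue_mass")
  perc_cap <- attr(prof_df, "perc_cap")
  bund <- attr(prof_df, "bund")
  drain_frac <- attr(prof_df, "drain_frac")
  p <- as.list(prof_df) # list-of-vectors layer state for the hot loop
  ret <- retention_params(p$wcst, p$wcfc, p$wcwp)
  cap_mm <- p$thickness * 1000
  z_top <- cumsum(p$thickness) - p$thickness

  ## residue incorporation at establishment: C and N enter the surface fom
  ## pool; the mass also insulates the surface (thermal bookkeeping only)
  res_n_in <- 0
  if (mgmt$residue_in$mass > 0) {
    rc <- ks$root_c_frac * mgmt$residue_in$mass
    rn <- rc / mgmt$residue_in$cn
    p$fom_c[1] <- p$fom_c[1] + rc
    p$fom_n[1] <- p$fom_n[1] + rn
    residue <- residue + mgmt$residue_in$mass
    res_n_in <- rn
  }

  ## initial crop state
  est <- mgmt$establishment
  sla0 <- interp_table(cult$sla_table, 0)
  crop <- list(dvs = 0, tsum = 0,
               wlvg = est$init_wlvg, wlvd = 0, wst = est$init_wst, wso = 0,
               lai = est$init_wlvg * sla0 / 1e4,
               leaf_n_mass = 0, stem_n = 0, pan_n = 0, wlvd_n = 0,
               root_depth = min(p$thickness[1], cult$d_max))
  crop$leaf_n_mass <- cult$n_crit_leaf * crop$lai * 10
  crop$stem_n <- interp_table(cult$n_crit_stem_table, 0) * crop$wst
  p$root_mass[1] <- est$init_root
  p$root_n[1] <- ks$root_c_frac / cult$root_cn_opt * est$init_root

  t0 <- mean(c(wtr$tmin[1], wtr$tmax[1]))

  total_n <- function(p, cr) {
    sum(p$fom_n + p$hum_n + p$urea_n + p$nh4_n + p$no3_n + p$root_n) +
      cr$leaf_n_mass + cr$stem_n + cr$pan_n + cr$wlvd_n
  }
  w_store0 <- sum(p$theta * cap_mm) + standing
  n_store0 <- total_n(p, crop) - res_n_in # residue N counted as an input

  cum <- list(rain = 0, irrigation = 0, transp = 0, evap = 0, perc = 0,
              runoff = 0, co2 = 0, n2o = 0, nh3 = 0, denit = 0, nleach = 0,
              ndep = 0, fert = 0, residue_n = res_n_in)
  ndays <- nrow(wtr)
  scalar_cols <- c("dae", "dvs", "tsum", "wagt", "wso", "wst", "wlvg",
                   "wlvd", "lai", "leaf_n", "sw", "sn", "root_depth",
                   "root_mass", "standing_water", "irrigation", "rain",
                   "et_pot", "transp", "evap", "cum_transp", "cum_evap",
                   "cum_perc", "cum_runoff", "cum_irrigation", "cum_rain",
                   "cum_co2", "cum_n2o", "cum_nh3", "cum_denit",
                   "cum_nleach", "cum_ndep", "cum_fert", "n_uptake",
                   "n_demand", "water_resid", "n_resid")
  layer_cols <- paste0(rep(c("theta_", "temp_", "psi_", "nh4_", "no3_",
                             "urea_", "root_"), each = nl),
                       rep(seq_len(nl), times = 7))
  out <- matrix(NA_real_, ndays, length(scalar_cols) + length(layer_cols),
                dimnames = list(NULL, c(scalar_cols, layer_cols)))
  last <- 0L

  for (d in seq_len(ndays)) {
    tmin <- wtr$tmin[d]; tmax <- wtr$tmax[d]
    srad <- wtr$srad[d]; rain <- wtr$rain[d]
    tmean <- (tmin + tmax) / 2

    ## -- potential ET (Priestley-Taylor), partitioned by Beer's law --
    es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
    delta <- 4098 * es / (tmean + 237.3)^2
    et_pot <- max(0, ks$pt_alpha * delta / (delta + ks$psych_gamma) *
                    ks$rn_fraction * srad / ks$lambda_vap)
    e_pot <- et_pot * exp(-cult$k_ext * crop$lai)
    t_pot <- et_pot - e_pot

    ## -- soil temperature --
    k_th <- thermal_conductance(p$clay, p$sand, p$theta, ks)
    h_th <- heat_capacity(pmin(p$theta, 1 - p$bd / 2.65), p$bd, ks)
    sb <- surface_boundary(tmean, t0, standing, residue, k_th[1], h_th[1], ks)
    t0 <- sb$t0
    st <- step_temperature(p$temp, p$z_mid, p$thickness, k_th, h_th,
                           sb$t0, sb$k0, dt = 86400,
                           substeps = cfg$substeps_heat)
    p$temp <- st$temp
    temp_day <- st$temp_mean

    ## -- soil C/N transformations --
    day_co2 <- day_n2o <- day_nh3 <- day_den <- 0
    for (i in seq_len(nl)) {
      li <- list(urea_n = p$urea_n[i], nh4_n = p$nh4_n[i], no3_n = p$no3_n[i],
                 fom_c = p$fom_c[i], fom_n = p$fom_n[i],
                 hum_c = p$hum_c[i], hum_n = p$hum_n[i])
      mods <- rate_modifiers(p$temp[i], p$theta[i], p$wcst[i], p$wcfc[i],
                             p$wcwp[i], ks)
      li <- hydrolyse_urea(li, mods$ft, constants = ks)$layer
      dc <- decompose_om(li, mods$ft, mods$fw, constants = ks)
      li <- dc$layer
      nd <- nitrify_denitrify(li, mods$ft, mods$fw, p$theta[i], p$wcst[i],
                              p$wcfc[i], p$ph[i], constants = ks)
      li <- nd$layer
      day_co2 <- day_co2 + dc$co2
      day_n2o <- day_n2o + nd$n2o
      day_den <- day_den + nd$denitrified
      if (i == 1) {
        vo <- volatilize(li, standing, p$ph[1], p$temp[1], constants = ks)
        li <- vo$layer
        day_nh3 <- day_nh3 + vo$nh3
        dp <- deposit(li, ks$deposition_rate)
        li <- dp$layer
        cum$ndep <- cum$ndep + dp$deposited
      }
      p$urea_n[i] <- li$urea_n; p$nh4_n[i] <- li$nh4_n; p$no3_n[i] <- li$no3_n
      p$fom_c[i] <- li$fom_c; p$fom_n[i] <- li$fom_n
      p$hum_c[i] <- li$hum_c; p$hum_n[i] <- li$hum_n
    }

    ## -- crop development and N demand --
    ph <- advance_phenology(crop$tsum, tmean, cult)
    crop$tsum <- ph$tsum
    crop$dvs <- ph$dvs
    dem <- n_demand(crop, sum(p$root_mass), sum(p$root_n), cult, ks)

    ## -- water uptake and drought index --
    rooted <- pmax(0, pmin(p$thickness, crop$root_depth - z_top))
    ew <- extractable_water(p$theta, p$wcwp, p$wcst, rooted, cult$dtf)
    up <- partition_uptake(t_pot, p$root_mass, ew)
    p$theta <- p$theta - up$uptake / cap_mm
    sw <- drought_index(up$total, t_pot, cult$dtf)
    cum$transp <- cum$transp + up$total

    ## -- nitrogen uptake and stress index --
    water_vol <- p$theta * cap_mm
    mineral <- p$nh4_n + p$no3_n
    mf <- mass_flow_uptake(up$uptake, mineral, water_vol)
    if (sum(mf) > dem$demand && sum(mf) > 0) mf <- mf * dem$demand / sum(mf)
    fw_wet <- clamp((p$theta - p$wcwp) / (p$wcfc - p$wcwp), 0, 1)
    df <- diffusion_uptake(max(0, dem$demand - sum(mf)), mineral - mf,
                           p$root_mass, fw_wet, ks)
    n_up_layer <- mf + df
    take_nh4 <- pmin(p$nh4_n, n_up_layer) # NH4 first, then NO3
    p$nh4_n <- p$nh4_n - take_nh4
    p$no3_n <- p$no3_n - (n_up_layer - take_nh4)
    n_uptake <- sum(n_up_layer)
    sn <- n_stress_index(n_uptake, dem$demand)
    defs <- dem$deficits
    if (sum(defs) > 0 && n_uptake > 0) {
      share <- defs / sum(defs) * n_uptake
      crop$leaf_n_mass <- crop$leaf_n_mass + share[["leaf"]]
      crop$stem_n <- crop$stem_n + share[["stem"]]
      crop$pan_n <- crop$pan_n + share[["panicle"]]
      rshare <- share[["root"]]
      if (rshare > 0) {
        rm_tot <- sum(p$root_mass)
        if (rm_tot > 0) p$root_n <- p$root_n + rshare * p$root_mass / rm_tot
        else p$root_n[1] <- p$root_n[1] + rshare
      }
    }

    ## -- photosynthesis and allocation --
    sw_eff <- if (use_sw) sw else 1
    sn_eff <- if (use_sn) sn else 1
    gross <- daily_growth(srad, crop$lai, cult, sw_eff, sn_eff)
    al <- allocate_biomass(gross, crop$dvs, sw_eff, sn_eff, crop$lai, cult, ks)
    crop$wst <- crop$wst + al$stem
    crop$wso <- crop$wso + al$panicle
    crop <- update_canopy(crop, al$leaf, sw_eff, sn_eff, cult, ks)

    ## -- root growth and senescence --
    front_i <- which(cumsum(p$thickness) >= crop$root_depth - 1e-9)[1]
    if (is.na(front_i)) front_i <- nl
    fi <- min(front_i + 1, nl)
    front_layer <- list(theta = p$theta[fi], wcwp = p$wcwp[fi],
                        wcfc = p$wcfc[fi], clay = p$clay[fi], bd = p$bd[fi])
    crop$root_depth <- extend_root_front(crop$root_depth, cult, temp_day[1],
                                         front_layer, constants = ks)
    inc <- distribute_root_growth(al$root, p, crop$root_depth, cult, ks)
    p$root_mass <- p$root_mass + inc
    for (i in which(p$root_mass > 0)) {
      sen <- senesce_roots(p$root_mass[i], p$root_n[i], cult$root_cn_opt,
                           constants = ks)
      p$root_mass[i] <- sen$root_mass
      p$root_n[i] <- sen$root_n
      p$fom_c[i] <- p$fom_c[i] + sen$fom_c_add
      p$fom_n[i] <- p$fom_n[i] + sen$fom_n_add
    }

    ## -- water redistribution and N transport --
    ws <- step_water(p, standing, infil = rain, evap_pot = e_pot,
                     perc_cap = perc_cap, bund = bund,
                     drain_frac = drain_frac)
    p$theta <- ws$profile$theta
    standing <- ws$standing_water
    tr <- transport_n(p, ws$flux_down, ks)
    p$urea_n <- tr$profile$urea_n
    p$nh4_n <- tr$profile$nh4_n
    p$no3_n <- tr$profile$no3_n
    cum$evap <- cum$evap + ws$evap
    cum$perc <- cum$perc + ws$percolation
    cum$runoff <- cum$runoff + ws$runoff
    cum$rain <- cum$rain + rain
    cum$nleach <- cum$nleach + tr$n_leach
    cum$co2 <- cum$co2 + day_co2
    cum$n2o <- cum$n2o + day_n2o
    cum$nh3 <- cum$nh3 + day_nh3
    cum$denit <- cum$denit + day_den

    ## -- management events --
    mg <- apply_management(d, crop$dvs, mgmt, p, standing)
    p$urea_n <- mg$profile$urea_n
    p$nh4_n <- mg$profile$nh4_n
    standing <- standing + mg$irrigation
    cum$irrigation <- cum$irrigation + mg$irrigation
    cum$fert <- cum$fert + mg$n_applied

    ## -- invariants and closure audits --
    if (any(p$theta < p$wcwp - 1e-9) || any(p$theta > p$wcst + 1e-9)) {
      stop("soil water content out of bounds on day ", d)
    }
    if (min(crop$wlvg, crop$wlvd, crop$wst, crop$wso) < -1e-9 ||
        any(p$root_mass < -1e-9)) {
      stop("negative biomass pool on day ", d)
    }
    w_resid <- (sum(p$theta * cap_mm) + standing) - w_store0 -
      (cum$rain + cum$irrigation - cum$transp - cum$evap - cum$perc -
         cum$runoff)
    n_resid <- total_n(p, crop) - n_store0 -
      (cum$fert + cum$ndep + cum$residue_n - cum$nleach - cum$nh3 - cum$denit)

    psi <- swc_to_potential(pmax(p$theta, 1e-6), p$wcst, ret)
    wagt <- crop$wlvg + crop$wlvd + crop$wst + crop$wso
    leaf_n_sp <- if (crop$lai > 0) crop$leaf_n_mass / (crop$lai * 10) else 0
    out[d, ] <- c(d, crop$dvs, crop$tsum, wagt, crop$wso, crop$wst,
                  crop$wlvg, crop$wlvd, crop$lai, leaf_n_sp, sw, sn,
                  crop$root_depth, sum(p$root_mass), standing,
                  mg$irrigation, rain, et_pot, up$total, ws$evap,
                  cum$transp, cum$evap, cum$perc, cum$runoff,
                  cum$irrigation, cum$rain, cum$co2, cum$n2o, cum$nh3,
                  cum$denit, cum$nleach, cum$ndep, cum$fert,
                  n_uptake, dem$demand, w_resid, n_resid,
                  p$theta, temp_day, psi, p$nh4_n, p$no3_n, p$urea_n,
                  p$root_mass)
    last <- d
    if (crop$dvs >= 2) break
  }

  daily <- as.data.frame(out[seq_len(last), , drop = FALSE])
  daily <- cbind(date = wtr$date[seq_len(last)], daily)
  final <- list(
    days = last, maturity = crop$dvs >= 2,
    wagt = daily$wagt[last], wso = crop$wso,
    yield = crop$wso / ks$moisture_yield / 1000, # t ha-1 at 14% moisture
    max_water_resid = max(abs(daily$water_resid)),
    final_n_resid = daily$n_resid[last],
    max_n_resid = max(abs(daily$n_resid))
  )
  prof_end <- prof_df
  for (nm in setdiff(names(p), names(prof_end))) prof_end[[nm]] <- NULL
  for (nm in names(prof_end)) prof_end[[nm]] <- p[[nm]]
  attr(prof_end, "standing_water") <- standing
  structure(list(daily = daily, final = final, config = cfg,
                 production = production, profile_end = prof_end),
            class = "paddy_season")
}

#' @export
print.paddy_season <- function(x, ...) {
  f <- x$final
  cat("<paddy_season> ", f$days, " simulated days",
      if (f$maturity) " (reached maturity)" else " (season truncated)", "\n",
      sep = "")
  cat(sprintf("  final WAGT: %.0f kg ha-1   WSO: %.0f kg ha-1   yield: %.2f t ha-1\n",
              f$wagt, f$wso, f$yield))
  cat(sprintf("  max |water residual|: %.2e mm   max |N residual|: %.2e kg ha-1\n",
              f$max_water_resid, f$max_n_resid))
  invisible(x)
}

#' @export
summary.paddy_season <- function(object, ...) {
  d <- object$daily
  out <- list(
    final = object$final,
    stress_days = sum(pmin(d$sw, d$sn) < 0.95),
    mean_sw = mean(d$sw), mean_sn = mean(d$sn),
    water_in = d$cum_rain[nrow(d)] + d$cum_irrigation[nrow(d)],
    et = d$cum_transp[nrow(d)] + d$cum_evap[nrow(d)],
    n_leached = d$cum_nleach[nrow(d)],
    co2 = d$cum_co2[nrow(d)], n2o = d$cum_n2o[nrow(d)]
  )
  class(out) <- "summary.paddy_season"
  out
}

#' @export
print.summary.paddy_season <- function(x, ...) {
  cat(sprintf("yield %.2f t ha-1 over %d days; %d stressed days (min(Sw,SN) < 0.95)\n",
              x$final$yield, x$final$days, x$stress_days))
  cat(sprintf("mean Sw %.3f, mean SN %.3f; water in %.0f mm, ET %.0f mm\n",
              x$mean_sw, x$mean_sn, x$water_in, x$et))
  cat(sprintf("N leached %.1f kg ha-1; CO2 %.0f kg C ha-1; N2O %.3f kg N ha-1\n",
              x$n_leached, x$co2, x$n2o))
  invisible(x)
}

#' @export
plot.paddy_season <- function(x, ...) {
  d <- x$daily
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(d$dae, d$wagt, type = "l", xlab = "days after emergence",
                 ylab = "biomass (kg ha-1)", main = "Organ biomass")
  graphics::lines(d$dae, d$wso, lty = 2)
  graphics::lines(d$dae, d$wlvg, lty = 3)
  graphics::legend("topleft", c("WAGT", "WSO", "WLVG"), lty = 1:3, bty = "n")
  graphics::plot(d$dae, d$lai, type = "l", xlab = "days after emergence",
                 ylab = "LAI", main = "Leaf area index")
  graphics::plot(d$dae, pmin(d$sw, d$sn), type = "l", ylim = c(0, 1),
                 xlab = "days after emergence", ylab = "stress factor",
                 main = "min(Sw, SN)")
  graphics::plot(d$dae, d$theta_1, type = "l", xlab = "days after emergence",
                 ylab = "theta (m3 m-3)", main = "Surface soil water")
  invisible(x)
}
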