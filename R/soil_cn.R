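#' Temperature and moisture modifiers of microbial rates
#'
#' `ft` is a Q10 = 2 response referenced at 25 degC, capped at 1.2. `fw` rises
#' linearly from 0 at wilting point to 1 at field capacity, then declines
#' linearly to an anaerobic value at saturation (for decomposition and
#' nitrification). `fw_wet` is the simple 0-1 wetness ramp used where wetter
#' is never worse (root favorability, diffusive uptake).
#'
#' @param temp layer temperature, deg C
#' @param theta water content, m3 m-3
#' @param wcst,wcfc,wcwp layer water constants
#' @param constants list from [default_constants()]
#' @return list with `ft`, `fw`, `fw_wet`
#' @export
rate_modifiers <- function(temp, theta, wcst, wcfc, wcwp,
                           constants = default_constants()) {
  ft <- pmin(constants$q10^((temp - constants$t_ref) / 10), constants$ft_cap)
  ramp <- clamp((theta - wcwp) / (wcfc - wcwp), 0, 1)
  wet <- clamp((theta - wcfc) / (wcst - wcfc), 0, 1)
  fw <- ramp * (1 - wet * (1 - constants$fw_anaerobic))
  list(ft = ft, fw = fw, fw_wet = ramp)
}

## first-order decay amount over dt days: exact exponential, or sub-stepped Euler
decay_amount <- function(pool, k, dt = 1, method = "exact", substeps = 24) {
  if (method == "exact") {
    pool * (1 - exp(-k * dt))
  } else {
    nsub <- max(1L, as.integer(substeps * dt))
    pool * (1 - (1 - k * dt / nsub)^nsub)
  }
}

#' Decompose fresh organic matter and humus in one layer
#'
#' First-order decay of fom C (`k_fom`) and humus C (`k_hum`), each scaled by
#' `ft * fw`. A fixed humification fraction of the decomposed fom C enters the
#' humus pool (with N at the microbial C:N); the remainder is respired as CO2.
#' Net mineral N release = fom N released - N demand of humified C; net demand
#' draws NH4 then NO3, and decomposition is rationed when mineral N is
#' insufficient.
#'
#' @param layer one-row list/data.frame with fom_c, fom_n, hum_c, hum_n,
#'   nh4_n, no3_n
#' @param ft,fw rate modifiers
#' @param dt days
#' @param method "exact" (default) or "euler"
#' @param constants list from [default_constants()]
#' @return list: updated pools and fluxes `co2` (kg C), `n_min_net` (kg N;
#'   negative = net immobilization)
#' @export
decompose_om <- function(layer, ft, fw, dt = 1, method = "exact",
                      constants = default_constants()) {
  ks <- constants
  dec_fom <- decay_amount(layer$fom_c, ks$k_fom * ft * fw, dt, method, ks$euler_substeps)
  dec_hum <- decay_amount(layer$hum_c, ks$k_hum * ft * fw, dt, method, ks$euler_substeps)
  hum_in <- ks$humification * dec_fom
  n_fom_ratio <- if (layer$fom_c > 0) layer$fom_n / layer$fom_c else 0
  n_release <- dec_fom * n_fom_ratio
  n_immob <- hum_in / ks$micro_cn
  net <- n_release - n_immob
  if (net < 0) {
    need <- -net
    avail <- layer$nh4_n + layer$no3_n
    if (avail < need) {
      # ration: scale fom decomposition so immobilization fits available N
      scale <- if (need > 0) avail / need else 0
      # releases scale linearly with dec_fom, so scale the whole fom step
      dec_fom <- dec_fom * scale
      hum_in <- hum_in * scale
      n_release <- n_release * scale
      n_immob <- n_immob * scale
      net <- n_release - n_immob # = -avail
    }
  }
  n_hum_release <- if (layer$hum_c > 0) dec_hum * layer$hum_n / layer$hum_c else 0
  co2 <- (dec_fom - hum_in) + dec_hum
  layer$fom_c <- layer$fom_c - dec_fom
  layer$fom_n <- layer$fom_n - n_release
  layer$hum_c <- layer$hum_c + hum_in - dec_hum
  layer$hum_n <- layer$hum_n + n_immob - n_hum_release
  mineral_delta <- net + n_hum_release
  if (mineral_delta >= 0) {
    layer$nh4_n <- layer$nh4_n + mineral_delta
  } else {
    take_nh4 <- min(layer$nh4_n, -mineral_delta)
    layer$nh4_n <- layer$nh4_n - take_nh4
    layer$no3_n <- layer$no3_n - (-mineral_delta - take_nh4)
  }
  list(layer = layer, co2 = co2, n_min_net = mineral_delta)
}

#' Urea hydrolysis in one layer
#'
#' First-order transfer of urea N to NH4, rate `k_hyd * ft`.
#'
#' @inheritParams decompose_om
#' @return list: updated layer, `hydrolysed` kg N
#' @export
hydrolyse_urea <- function(layer, ft, dt = 1, method = "exact",
                           constants = default_constants()) {
  stopifnot(layer$urea_n >= 0)
  amt <- decay_amount(layer$urea_n, constants$k_hyd * ft, dt, method,
                      constants$euler_substeps)
  layer$urea_n <- layer$urea_n - amt
  layer$nh4_n <- layer$nh4_n + amt
  list(layer = layer, hydrolysed = amt)
}

#' Nitrification and denitrification in one layer
#'
#' Nitrification is first order in NH4 (`k_nit * ft * fw * f_pH`), suppressed
#' near saturation (theta >= 0.95 WCST). Denitrification is first order in NO3,
#' active only above field capacity, scaling with the saturation excess and
#' with fresh-C availability; denitrified N leaves as gas. Fixed fractions of
#' both fluxes are tallied as N2O for reporting and do not feed back.
#'
#' @inheritParams decompose_om
#' @param fw_nit moisture factor for nitrification
#' @param theta,wcst,wcfc layer water state
#' @param ph soil pH
#' @return list: updated layer, `nitrified`, `denitrified`, `n2o` kg N
#' @export
nitrify_denitrify <- function(layer, ft, fw_nit, theta, wcst, wcfc, ph,
                              dt = 1, method = "exact",
                              constants = default_constants()) {
  ks <- constants
  f_ph <- clamp((ph - 4) / 3, 0, 1)
  k_n <- ks$k_nit * ft * fw_nit * f_ph
  if (theta >= 0.95 * wcst) k_n <- 0
  nit <- decay_amount(layer$nh4_n, k_n, dt, method, ks$euler_substeps)
  layer$nh4_n <- layer$nh4_n - nit
  layer$no3_n <- layer$no3_n + nit

  den <- 0
  if (theta > wcfc) {
    f_an <- (theta - wcfc) / (wcst - wcfc)
    f_c <- layer$fom_c / (layer$fom_c + ks$den_c_half)
    den <- decay_amount(layer$no3_n, ks$k_den * ft * f_an * f_c, dt, method,
                        ks$euler_substeps)
    layer$no3_n <- layer$no3_n - den
  }
  n2o <- ks$n2o_frac_nit * nit + ks$n2o_frac_den * den
  list(layer = layer, nitrified = nit, denitrified = den, n2o = n2o)
}

#' Ammonia volatilization from the surface layer
#'
#' First-order loss from surface NH4; base rate at pH 7, doubling per pH unit,
#' zero below pH 5.5, doubled when standing water is present.
#'
#' @inheritParams decompose_om
#' @param standing_water pond depth, mm
#' @param ph soil pH
#' @param temp surface layer temperature, deg C
#' @return list: updated layer, `nh3` kg N
#' @export
volatilize <- function(layer, standing_water, ph, temp, dt = 1,
                       method = "exact", constants = default_constants()) {
  ks <- constants
  if (ph < ks$vol_ph_min) {
    return(list(layer = layer, nh3 = 0))
  }
  k <- ks$k_vol * 2^(ph - 7) *
    pmin(ks$q10^((temp - ks$t_ref) / 10), ks$ft_cap)
  if (standing_water > 0) k <- k * ks$vol_water_mult
  amt <- decay_amount(layer$nh4_n, k, dt, method, ks$euler_substeps)
  layer$nh4_n <- layer$nh4_n - amt
  list(layer = layer, nh3 = amt)
}

#' Advective transport of mineral N with water fluxes
#'
#' Urea and NO3 move with the water at the source layer's dissolved
#' concentration; NH4 mobility is damped by an adsorption factor. Organic
#' pools are immobile. Fluxes are processed top-down so percolating water can
#' carry N through several layers in one day; mass leaving the bottom
#' interface is leached N.
#'
#' @param profile soil profile data frame
#' @param flux_down mm of water crossing the bottom of each layer (from
#'   [step_water()])
#' @param constants list from [default_constants()]
#' @return list: updated profile, `n_leach` kg N ha-1
#' @export
transport_n <- function(profile, flux_down, constants = default_constants()) {
  n <- length(profile$theta)
  mob <- constants$nh4_mobility
  leach <- 0
  for (i in seq_len(n)) {
    w <- flux_down[i]
    if (w <= 0) next
    vol <- profile$theta[i] * profile$thickness[i] * 1000
    frac <- if (vol > 0) min(1, w / vol) else 1
    for (pool in c("urea_n", "no3_n", "nh4_n")) {
      f <- if (pool == "nh4_n") frac * mob else frac
      moved <- min(profile[[pool]][i], profile[[pool]][i] * f)
      profile[[pool]][i] <- profile[[pool]][i] - moved
      if (i < n) {
        profile[[pool]][i + 1] <- profile[[pool]][i + 1] + moved
      } else {
        leach <- leach + moved
      }
    }
  }
  list(profile = profile, n_leach = leach)
}

#' Atmospheric nitrogen deposition onto the surface layer
#'
#' The annual rate is applied as a constant daily increment, split 50:50
#' between NH4 and NO3.
#'
#' @param layer surface layer
#' @param rate annual deposition, kg N ha-1 yr-1
#' @param dt days
#' @return list: updated layer, `deposited` kg N
#' @export
deposit <- function(layer, rate = 10, dt = 1) {
  stopifnot(rate >= 0)
  add <- rate / 365 * dt
  layer$nh4_n <- layer$nh4_n + add / 2
  layer$no3_n <- layer$no3_n + add / 2
  list(layer = layer, deposited = add)
}
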