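#' Default process constants
#'
#' All empirical rate constants and response-curve coefficients used by the
#' soil and crop process routines, collected in one place and overridable per
#' run through [sim_config()]'s `constants` argument. Units are noted for each
#' entry. These are documented model defaults; the process forms they
#' parameterize are described in the methods vignette.
#'
#' @return Named list of constants.
#' @export
default_constants <- function() {
  list(
    ## -- energy balance / ET --
    pt_alpha       = 1.26,    # Priestley-Taylor coefficient, unitless
    rn_fraction    = 0.75,    # net radiation as fraction of incoming shortwave
    psych_gamma    = 0.066,   # psychrometric constant, kPa K-1
    lambda_vap     = 2.45,    # latent heat of vaporization, MJ kg-1

    ## -- soil heat --
    c_solid        = 2.0e6,   # volumetric heat capacity of solids, J m-3 K-1 (at BD 2.65)
    c_water        = 4.18e6,  # volumetric heat capacity of water, J m-3 K-1
    k_dry_base     = 0.25,    # thermal conductivity of dry soil, W m-1 K-1
    k_sat_sand     = 2.2,     # saturated conductivity, sand end member, W m-1 K-1
    k_sat_clay     = 1.2,     # saturated conductivity, clay end member, W m-1 K-1
    k_water        = 0.57,    # thermal conductivity of water, W m-1 K-1
    h_water        = 4.18e6,  # heat capacity of ponded water, J m-3 K-1
    surf_damp_water = 20,     # mm of standing water halving surface coupling
    surf_damp_residue = 2000, # kg ha-1 of residue halving surface coupling

    ## -- soil water --
    drain_frac     = 0.5,     # fraction of water above WCFC draining per day
    perc_cap_lowland = 5,     # max percolation below profile, mm d-1 (puddled)
    perc_cap_aerobic = 20,    # max percolation below profile, mm d-1
    bund_height    = 100,     # bund (pond) height, mm, lowland default

    ## -- soil C/N --
    q10            = 2,       # temperature sensitivity of microbial rates
    t_ref          = 25,      # reference temperature, deg C
    ft_cap         = 1.2,     # upper cap on the Q10 factor
    fw_anaerobic   = 0.3,     # moisture factor at saturation (decomposition/nitrification)
    k_fom          = 0.02,    # fresh organic matter decay, d-1
    k_hum          = 5e-5,    # humus decay, d-1
    humification   = 0.3,     # fraction of decomposed fom C entering humus
    micro_cn       = 10,      # microbial / humus C:N forced on assimilated C
    k_hyd          = 0.25,    # urea hydrolysis, d-1
    k_nit          = 0.2,     # nitrification, d-1
    k_den          = 0.1,     # denitrification, d-1
    den_c_half     = 500,     # half-saturation of denitrification on fom C, kg C ha-1
    n2o_frac_nit   = 0.005,   # reported N2O fraction of nitrified N (diagnostic only)
    n2o_frac_den   = 0.02,    # reported N2O fraction of denitrified N (diagnostic only)
    k_vol          = 0.05,    # NH3 volatilization base rate at pH 7, d-1
    vol_ph_min     = 5.5,     # no volatilization below this pH
    vol_water_mult = 2,       # multiplier when standing water present
    nh4_mobility   = 0.1,     # advective mobility of NH4 relative to NO3/urea
    deposition_rate = 10,     # atmospheric N deposition, kg N ha-1 yr-1
    euler_substeps = 24,      # sub-steps per day in Euler update mode

    ## -- roots --
    root_c_frac    = 0.42,    # g C g-1 root dry matter
    root_ext_rate  = 0.01,    # base root front extension, m d-1
    root_sen_max   = 0.05,    # max fraction of root mass senescing per day
    root_n_resorb  = 0.5,     # fraction of N resorbed from senescing roots
    root_fn_half   = 20,      # half-saturation of root N attraction, kg N ha-1 layer-1

    ## -- N uptake --
    d_coef         = 0.2,     # diffusive uptake coefficient, d-1

    ## -- canopy --
    leaf_death_base = 0.01,   # relative leaf death rate after flowering, d-1
    leaf_n_recycle  = 0.5,    # fraction of dying-leaf N recycled to green leaves
    lai_crowd       = 6,      # LAI above which leaf share shifts to stem+panicle
    crowd_shift     = 0.1,    # fraction of leaf share shifted when crowded
    root_shift_floor = 0.5,   # shoot-fraction stress multiplier floor
    moisture_yield  = 0.86    # dry-to-14%-moisture grain yield conversion
  )
}

## linear interpolation in a two-column table (x strictly increasing), clamped
interp_table <- function(tab, x) {
  stats::approx(tab[, 1], tab[, 2], xout = x, rule = 2)$y
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
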