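#' Daily extension of the root front
#'
#' Extension = base rate x temperature factor (cultivar cardinal temperatures)
#' x penetration factor (decreasing with bulk density and clay of the layer
#' being entered) x moisture factor (zero below wilting point at the front),
#' capped at the cultivar's maximum rooting depth.
#'
#' @param depth current root depth, m
#' @param cultivar list from [cultivar_params()]
#' @param temp_surface surface-layer temperature, deg C
#' @param front_layer list/row for the layer the front is entering (theta,
#'   wcwp, wcfc, clay, bd)
#' @param dt days
#' @param constants list from [default_constants()]
#' @param legacy if TRUE, constant-rate downward growth (old-model contrast
#'   behaviour), still capped at D_max
#' @return new depth, m
#' @export
extend_root_front <- function(depth, cultivar, temp_surface, front_layer,
                              dt = 1, constants = default_constants(),
                              legacy = FALSE) {
  stopifnot(depth <= cultivar$d_max + 1e-12)
  base <- constants$root_ext_rate * dt
  if (legacy) return(min(depth + base, cultivar$d_max))
  f_t <- thermal_factor(temp_surface, cultivar$tbase, cultivar$topt, cultivar$thigh) /
    (cultivar$topt - cultivar$tbase)
  pen <- clamp(1 - max(0, front_layer$bd - 1.1) / 0.9, 0, 1) *
    (1 - 0.5 * front_layer$clay)
  f_w <- if (front_layer$theta <= front_layer$wcwp) 0 else
    clamp((front_layer$theta - front_layer$wcwp) /
            (front_layer$wcfc - front_layer$wcwp), 0, 1)
  min(depth + base * f_t * pen * f_w, cultivar$d_max)
}

#' Distribute new root dry matter over rooted layers
#'
#' Increments are proportional to a favorability weight per layer:
#' moisture factor x temperature factor x a saturating (Michaelis-type)
#' mineral-N factor x rooted thickness, normalized so the increments sum to
#' the new dry matter exactly. If all weights vanish, distribution falls back
#' to uniform per rooted thickness.
#'
#' @param new_root_dm kg ha-1 of new root dry matter
#' @param profile soil profile data frame
#' @param root_depth current root front, m
#' @param cultivar list from [cultivar_params()]
#' @param constants list from [default_constants()]
#' @return per-layer increments, kg ha-1 (length nrow(profile))
#' @export
distribute_root_growth <- function(new_root_dm, profile, root_depth, cultivar,
                                   constants = default_constants()) {
  stopifnot(new_root_dm >= 0)
  n <- length(profile$theta)
  z_top <- cumsum(profile$thickness) - profile$thickness
  rooted <- pmax(0, pmin(profile$thickness, root_depth - z_top))
  if (new_root_dm == 0 || all(rooted == 0)) return(numeric(n))
  f_w <- clamp((profile$theta - profile$wcwp) / (profile$wcfc - profile$wcwp), 0, 1)
  f_t <- clamp(thermal_factor(profile$temp, cultivar$tbase, cultivar$topt,
                              cultivar$thigh) / (cultivar$topt - cultivar$tbase), 0, 1)
  nmin <- profile$urea_n + profile$nh4_n + profile$no3_n
  f_n <- nmin / (nmin + constants$root_fn_half)
  w <- f_w * f_t * f_n * rooted
  if (sum(w) <= 0) w <- rooted # uniform fallback per rooted thickness
  new_root_dm * w / sum(w)
}

#' Nitrogen-driven root senescence in one layer
#'
#' When the living root C:N ratio (C = 0.42 x dry matter) exceeds the
#' cultivar's optimum, biomass is shed to move the ratio back toward the
#' optimum, at most 5% of root mass per day. Half of the N in senescing
#' tissue is resorbed into the living root N pool; the rest leaves with the
#' dead tissue. Dead roots enter the layer's fresh organic matter pools.
#'
#' @param root_mass living root dry matter, kg ha-1
#' @param root_n living root N, kg ha-1
#' @param root_cn_opt optimal root C:N ratio
#' @param dt days
#' @param constants list from [default_constants()]
#' @return list: `dead_dm`, `root_mass`, `root_n`, `fom_c_add`, `fom_n_add`
#' @export
senesce_roots <- function(root_mass, root_n, root_cn_opt, dt = 1,
                          constants = default_constants()) {
  stopifnot(root_mass >= 0, root_n >= 0)
  cf <- constants$root_c_frac
  rho <- constants$root_n_resorb
  out <- list(dead_dm = 0, root_mass = root_mass, root_n = root_n,
              fom_c_add = 0, fom_n_add = 0)
  if (root_mass <= 0 || root_n <= 0) return(out)
  ratio <- cf * root_mass / root_n
  if (ratio <= root_cn_opt) return(out)
  conc <- root_n / root_mass
  # solve shed s so that cf(m - s) / (n - (1-rho) s conc) = opt
  s <- root_mass * (cf - root_cn_opt * conc) / (cf - (1 - rho) * root_cn_opt * conc)
  s <- clamp(s, 0, constants$root_sen_max * root_mass * dt)
  n_shed <- (1 - rho) * s * conc
  out$dead_dm <- s
  out$root_mass <- root_mass - s
  out$root_n <- root_n - n_shed
  out$fom_c_add <- cf * s
  out$fom_n_add <- n_shed
  out
}

## trapezoidal thermal response: 0 at/below tbase, rises to (topt - tbase) at
## topt, falls to 0 at thigh
thermal_factor <- function(temp, tbase, topt, thigh) {
  ifelse(temp <= tbase | temp >= thigh, 0,
         ifelse(temp <= topt, temp - tbase,
                (topt - tbase) * (thigh - temp) / (thigh - topt)))
}
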