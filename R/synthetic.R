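#' Generate a synthetic daily weather series
#'
#' Sinusoidal annual temperature with AR(1) day-to-day noise; rain occurrence
#' from a two-state Markov chain with gamma-distributed wet-day amounts
#' rescaled so the realized seasonal total matches the target (within a small
#' stochastic factor); radiation follows a seasonal clear-sky curve and is
#' reduced on wet days (cloud anticorrelation). Fully determined by the seed.
#'
#' @param days number of days
#' @param climate list: `t_mean` (annual/seasonal mean, deg C), `t_amplitude`
#'   (annual half-range, deg C), `t_diurnal` (daily tmax - tmin, deg C),
#'   `srad_mean` (MJ m-2 d-1), `rain_total` (mm per `days`), `wet_day_prob`,
#'   `start_doy` (day of year of day 1)
#' @param seed integer seed
#' @return data frame: date, tmin, tmax, srad, rain
#' @export
gen_weather <- function(days,
                        climate = list(t_mean = 27, t_amplitude = 3,
                                       t_diurnal = 9, srad_mean = 18,
                                       rain_total = 600, wet_day_prob = 0.4,
                                       start_doy = 152),
                        seed = 1L) {
  stopifnot(days >= 1)
  cl <- utils::modifyList(list(t_mean = 27, t_amplitude = 3, t_diurnal = 9,
                               srad_mean = 18, rain_total = 600,
                               wet_day_prob = 0.4, start_doy = 152), climate)
  set.seed(as.integer(seed))
  doy <- (cl$start_doy + seq_len(days) - 2) %% 365 + 1
  season <- sin(2 * pi * (doy - 105) / 365) # warm peak mid-April-ish shifted
  ar <- stats::filter(stats::rnorm(days, 0, 1.2), 0.6, method = "recursive")
  tmean <- cl$t_mean + cl$t_amplitude * season + as.numeric(ar)

  ## two-state Markov rain occurrence with stationary prob = wet_day_prob
  p <- cl$wet_day_prob
  p_ww <- min(0.95, p + 0.3 * (1 - p)) # persistence
  p_dw <- if (p < 1) p * (1 - p_ww) / (1 - p) else 1
  wet <- logical(days)
  wet[1] <- stats::runif(1) < p
  for (i in seq_len(days - 1)) {
    pr <- if (wet[i]) p_ww else p_dw
    wet[i + 1] <- stats::runif(1) < pr
  }
  rain <- numeric(days)
  if (cl$rain_total > 0 && any(wet)) {
    amt <- stats::rgamma(sum(wet), shape = 2, rate = 1)
    target <- cl$rain_total * exp(stats::rnorm(1, 0, 0.02))
    rain[wet] <- amt / sum(amt) * target
  }

  ## radiation: seasonal clear sky, clouded on wet days
  clear <- cl$srad_mean * (1 + 0.25 * season) / (1 - 0.25 * 0.5 * p)
  srad <- clear * ifelse(wet, 0.5, 1) *
    exp(stats::rnorm(days, 0, 0.08))
  srad <- pmax(srad, 1)

  trange <- pmax(2, cl$t_diurnal * ifelse(wet, 0.7, 1))
  data.frame(date = as.Date("2020-01-01") + cl$start_doy - 1 + seq_len(days) - 1,
             tmin = round(tmean - trange / 2, 2),
             tmax = round(tmean + trange / 2, 2),
             srad = round(srad, 2),
             rain = round(rain, 2))
}

#' Default soil profiles for the scenario families
#'
#' `"lowland"`: puddled clay-loam paddy, 9 x 0.1 m layers, 100 mm bund, slow
#' percolation. `"aerobic"`: sandier, unbunded, freely draining.
#'
#' @param type "lowland" or "aerobic"
#' @return a [soil_profile()]
#' @export
default_soil <- function(type = c("lowland", "aerobic")) {
  type <- match.arg(type)
  if (type == "lowland") {
    soil_profile(thickness = rep(0.1, 9), clay = 0.35, sand = 0.25, bd = 1.3,
                 ph = 6.5, wcst = 0.50, wcfc = 0.38, wcwp = 0.18,
                 theta = 0.45, standing_water = 20,
                 perc_cap = 5, bund = 100)
  } else {
    soil_profile(thickness = rep(0.1, 9), clay = 0.15, sand = 0.55, bd = 1.45,
                 ph = 6.0, wcst = 0.44, wcfc = 0.30, wcwp = 0.12,
                 theta = 0.30, standing_water = 0,
                 perc_cap = 20, bund = 0)
  }
}

#' Generate the synthetic scenario families
#'
#' Four experiment designs as runnable configurations:
#' \describe{
#'   \item{WME}{water management: continuously flooded plus AWD at 20, 40 and
#'     70 kPa thresholds (50 mm dose, 0.18 m sensing depth), 120 kg N ha-1 in
#'     three equal splits, lowland soil, warm semi-arid season.}
#'   \item{NFM}{nitrogen management: the 16 split schedules (8 wet-season at
#'     DAE 12/34/56/80, 8 dry-season at DAE 12/34/54/76, totals 0-225 kg N
#'     ha-1), continuously flooded lowland.}
#'   \item{ARE}{aerobic rice: unbunded aerobic soil, 225 and 300 kg N ha-1 in
#'     3 equal splits, suction-triggered (40 kPa) or sparse fixed
#'     irrigation.}
#'   \item{MVD}{multi-variety drought: 7 cultivar variants spanning DTF 1-10,
#'     each paired fully-irrigated vs rainfed after panicle initiation,
#'     160 kg N ha-1 in 5 splits (30:30:30:30:40), dry season.}
#' }
#'
#' @param family "WME", "NFM", "ARE" or "MVD"
#' @param seed integer seed (drives the weather draw)
#' @param days season length for the weather series
#' @return named list of [sim_config()] objects
#' @export
gen_scenarios <- function(family = c("WME", "NFM", "ARE", "MVD"), seed = 1L,
                          days = 130) {
  family <- match.arg(family)
  seed <- as.integer(seed)
  n3 <- function(total, daes = c(12, 34, 56)) {
    data.frame(dae = daes, amount = rep(total / length(daes), length(daes)),
               form = "urea")
  }
  out <- list()
  if (family == "WME") {
    w <- gen_weather(days, list(t_mean = 29, t_amplitude = 2.5, t_diurnal = 9,
                                srad_mean = 20, rain_total = 560,
                                wet_day_prob = 0.35), seed)
    mk <- function(irr) sim_config(w, default_soil("lowland"),
                                   cultivar_params(dtf = 3),
                                   management_schedule(irrigation = irr,
                                                       n_events = n3(120)),
                                   seed = seed)
    out <- list(
      CF = mk(list(rule = "continuous_flooded", target_depth = 50)),
      AWD20 = mk(list(rule = "awd", threshold_kpa = 20, sense_depth = 0.18,
                      dose = 50, start_dae = 15)),
      AWD40 = mk(list(rule = "awd", threshold_kpa = 40, sense_depth = 0.18,
                      dose = 50, start_dae = 15)),
      AWD70 = mk(list(rule = "awd", threshold_kpa = 70, sense_depth = 0.18,
                      dose = 50, start_dae = 15))
    )
  } else if (family == "NFM") {
    splits <- list(
      WSN1 = c(0, 0, 0, 30), WSN2 = c(80, 0, 0, 30), WSN3 = c(40, 40, 0, 30),
      WSN4 = c(27, 27, 27, 30), WSN5 = c(0, 0, 0, 0), WSN6 = c(80, 0, 0, 0),
      WSN7 = c(40, 40, 0, 0), WSN8 = c(27, 27, 27, 0),
      DSN1 = c(0, 0, 0, 0), DSN2 = c(0, 0, 0, 45), DSN3 = c(60, 60, 60, 0),
      DSN4 = c(60, 60, 60, 45), DSN5 = c(60, 60, 0, 0),
      DSN6 = c(60, 60, 0, 45), DSN7 = c(0, 60, 60, 0), DSN8 = c(0, 60, 60, 45)
    )
    daes <- list(WS = c(12, 34, 56, 80), DS = c(12, 34, 54, 76))
    w_ws <- gen_weather(days, list(t_mean = 27.5, t_amplitude = 1.5,
                                   t_diurnal = 7, srad_mean = 16,
                                   rain_total = 950, wet_day_prob = 0.55), seed)
    w_ds <- gen_weather(days, list(t_mean = 26, t_amplitude = 1.5,
                                   t_diurnal = 8.5, srad_mean = 21,
                                   rain_total = 65, wet_day_prob = 0.08),
                        seed + 1L)
    for (code in names(splits)) {
      season <- substr(code, 1, 2)
      amt <- splits[[code]]
      keep <- amt > 0
      ev <- if (any(keep)) {
        data.frame(dae = daes[[season]][keep], amount = amt[keep],
                   form = "urea")
      } else {
        data.frame(dae = numeric(), amount = numeric(), form = character())
      }
      out[[code]] <- sim_config(
        if (season == "WS") w_ws else w_ds, default_soil("lowland"),
        cultivar_params(dtf = 2),
        management_schedule(
          irrigation = list(rule = "continuous_flooded", target_depth = 50),
          n_events = ev),
        seed = seed)
    }
  } else if (family == "ARE") {
    w <- gen_weather(days, list(t_mean = 25, t_amplitude = 4, t_diurnal = 11,
                                srad_mean = 17, rain_total = 590,
                                wet_day_prob = 0.3), seed)
    irr_w1 <- list(rule = "awd", threshold_kpa = 40, sense_depth = 0.15,
                   dose = 60, start_dae = 1)
    irr_w2 <- list(rule = "fixed_events",
                   events = data.frame(dae = c(5, 20, 35, 60),
                                       mm = c(60, 60, 60, 60)))
    for (nm in c("W1N1", "W1N2", "W2N1", "W2N2")) {
      ntot <- if (grepl("N1", nm)) 225 else 300
      irr <- if (grepl("W1", nm)) irr_w1 else irr_w2
      out[[nm]] <- sim_config(
        w, default_soil("aerobic"), cultivar_params(dtf = 5, d_max = 0.8),
        management_schedule(
          establishment = list(method = "direct-seed", density = 260,
                               init_wlvg = 30, init_wst = 20, init_root = 15),
          irrigation = irr, n_events = n3(ntot)),
        seed = seed)
    }
  } else { # MVD
    w <- gen_weather(days, list(t_mean = 26, t_amplitude = 2, t_diurnal = 7,
                                srad_mean = 21, rain_total = 260,
                                wet_day_prob = 0.15), seed)
    dtfs <- c(1, 2.5, 4, 5.5, 7, 8.5, 10)
    nev <- data.frame(dae = c(10, 25, 40, 55, 70),
                      amount = c(30, 30, 30, 30, 40), form = "urea")
    for (v in seq_along(dtfs)) {
      cv <- cultivar_params(dtf = dtfs[v])
      for (env in c("I", "D")) {
        irr <- if (env == "I") {
          list(rule = "continuous_flooded", target_depth = 50)
        } else {
          list(rule = "rainfed_after", dvs = 0.65, target_depth = 50)
        }
        out[[paste0("V", v, env)]] <- sim_config(
          w, default_soil("lowland"), cv,
          management_schedule(irrigation = irr, n_events = nev),
          seed = seed)
      }
    }
  }
  out
}

#' Potential-production (non-limiting) scenario
#'
#' The reference configuration in which neither water nor nitrogen limits
#' growth: a continuously flooded puddled soil whose mineral nitrogen supply
#' is made non-limiting by construction (saturating basal ammonium in every
#' layer plus 300 kg N ha-1 of urea in five splits), under benign warm
#' weather. Used to verify that the stress pathways are exactly inactive
#' when supply meets demand: in this scenario the stress indices stay at 1
#' and an `"actual"` run matches a `"potential"` run bit for bit.
#'
#' @param seed integer seed
#' @param days season length
#' @return a [sim_config()]
#' @export
scenario_potential <- function(seed = 1L, days = 130) {
  w <- gen_weather(days, list(t_mean = 28, t_amplitude = 2, t_diurnal = 8,
                              srad_mean = 19, rain_total = 400,
                              wet_day_prob = 0.3), seed)
  soil <- soil_profile(thickness = rep(0.1, 9), clay = 0.35, sand = 0.25,
                       bd = 1.3, ph = 6.5, wcst = 0.50, wcfc = 0.38,
                       wcwp = 0.18, theta = 0.45, standing_water = 20,
                       nh4_n = 100, perc_cap = 5, bund = 100)
  mg <- management_schedule(
    n_events = data.frame(dae = c(12, 34, 54, 76, 90),
                          amount = rep(60, 5), form = "urea"))
  sim_config(w, soil, cultivar_params(dtf = 3), mg, seed = seed)
}
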