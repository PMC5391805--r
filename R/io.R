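#' Read a daily weather file
#'
#' CSV with header `date,tmin,tmax,srad,rain` (ISO dates; deg C; MJ m-2 d-1;
#' mm). Malformed rows, duplicate or missing dates are rejected with the
#' offending line.
#'
#' @param path file path
#' @return validated weather data frame
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax", "srad", "rain")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("weather file missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("tmin", "tmax", "srad", "rain")) {
    v <- suppressWarnings(as.numeric(w[[col]]))
    bad <- which(is.na(v) & !is.na(w[[col]]))
    if (length(bad)) stop("weather file line ", bad[1] + 1,
                          ": non-numeric value in column '", col, "'")
    w[[col]] <- v
  }
  d <- as.Date(w$date)
  bad <- which(is.na(d))
  if (length(bad)) stop("weather file line ", bad[1] + 1,
                        ": unparseable date '", w$date[bad[1]], "'")
  w$date <- d
  bad <- which(w$tmax < w$tmin)
  if (length(bad)) stop("weather file line ", bad[1] + 1, ": tmax < tmin")
  validate_weather(w)
  w
}

#' Write a daily weather file
#'
#' @param weather weather data frame
#' @param path file path
#' @export
write_weather <- function(weather, path) {
  w <- weather
  w$date <- format(as.Date(w$date), "%Y-%m-%d")
  utils::write.csv(w[, c("date", "tmin", "tmax", "srad", "rain")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the daily output table of a season run
#'
#' CSV with a stable, documented column order (the column order of
#' `result$daily`).
#'
#' @param result a `paddy_season` or its `daily` data frame
#' @param path file path
#' @export
write_daily_output <- function(result, path) {
  d <- if (inherits(result, "paddy_season")) result$daily else result
  d$date <- format(as.Date(d$date), "%Y-%m-%d")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## variables observable against the daily output table
obs_variables <- c("wagt", "wso", "wst", "wlvg", "wlvd", "lai", "leaf_n")

#' Read an observation file
#'
#' CSV with header `date,variable,value`; `variable` must be one of the
#' observable output columns (wagt, wso, wst, wlvg, wlvd, lai, leaf_n).
#'
#' @param path file path
#' @return data frame date/variable/value
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  o <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("date", "variable", "value"), names(o))
  if (length(miss)) stop("observation file missing columns: ",
                         paste(miss, collapse = ", "))
  o$date <- as.Date(o$date)
  bad <- setdiff(unique(o$variable), obs_variables)
  if (length(bad)) stop("unknown observation variable(s): ",
                        paste(bad, collapse = ", "),
                        "; valid names: ", paste(obs_variables, collapse = ", "))
  o$value <- as.numeric(o$value)
  o
}

#' Join observations to simulated daily output
#'
#' Matches observation rows to simulation rows by date for one variable and
#' returns the paired series. The join is order-independent.
#'
#' @param sim a `paddy_season` or its daily table
#' @param obs observation data frame from [read_observations()]
#' @param variable which variable to pair
#' @return a [paired_series()]
#' @export
join_sim_obs <- function(sim, obs, variable) {
  d <- if (inherits(sim, "paddy_season")) sim$daily else sim
  if (!variable %in% obs_variables) {
    stop("unknown variable '", variable, "'; valid names: ",
         paste(obs_variables, collapse = ", "))
  }
  o <- obs[obs$variable == variable, , drop = FALSE]
  o <- o[order(o$date), , drop = FALSE]
  idx <- match(as.Date(o$date), as.Date(d$date))
  keep <- !is.na(idx)
  if (!any(keep)) stop("no observation dates overlap the simulated period")
  paired_series(o$value[keep], d[[variable]][idx[keep]], variable)
}

#' Read a run configuration file
#'
#' YAML document mirroring [sim_config()]: `weather` (path, relative to the
#' config file), `soil` (either `type: lowland|aerobic` or explicit
#' [soil_profile()] arguments), `cultivar` (overrides of
#' [cultivar_params()]), `management` (establishment / irrigation /
#' n_events / residue_in), `seed`, `substeps_heat`.
#'
#' @param path YAML file path
#' @return a [sim_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  wpath <- y$weather
  if (!is.null(wpath) && !file.exists(wpath)) wpath <- file.path(base, y$weather)
  weather <- read_weather(wpath)
  soil <- if (!is.null(y$soil$type)) default_soil(y$soil$type)
          else do.call(soil_profile, y$soil %||% list())
  cultivar <- do.call(cultivar_params, y$cultivar %||% list())
  m <- y$management %||% list()
  if (!is.null(m$n_events)) m$n_events <- as.data.frame(m$n_events)
  if (!is.null(m$irrigation$events)) {
    m$irrigation$events <- as.data.frame(m$irrigation$events)
  }
  management <- do.call(management_schedule, m)
  sim_config(weather, soil, cultivar, management,
             seed = y$seed %||% 1L, substeps_heat = y$substeps_heat %||% 24L)
}

#' Audit conservation of water and nitrogen in a season run
#'
#' Recomputes the worst daily water-balance residual and the seasonal
#' nitrogen-balance residual carried in the output table and checks both
#' against tight tolerances.
#'
#' @param result a `paddy_season`
#' @param tol_water mm
#' @param tol_n kg N ha-1
#' @return list with `water_resid`, `n_resid`, `ok`; printed nicely
#' @export
audit_balance <- function(result, tol_water = 1e-6, tol_n = 1e-6) {
  stopifnot(inherits(result, "paddy_season"))
  wr <- max(abs(result$daily$water_resid))
  nr <- max(abs(result$daily$n_resid))
  structure(list(water_resid = wr, n_resid = nr,
                 ok = wr < tol_water && nr < tol_n,
                 tol_water = tol_water, tol_n = tol_n),
            class = "balance_audit")
}

#' @export
print.balance_audit <- function(x, ...) {
  cat(sprintf("water balance: max |residual| = %.3e mm (tol %.0e) %s\n",
              x$water_resid, x$tol_water,
              if (x$water_resid < x$tol_water) "OK" else "FAIL"))
  cat(sprintf("nitrogen balance: max |residual| = %.3e kg ha-1 (tol %.0e) %s\n",
              x$n_resid, x$tol_n,
              if (x$n_resid < x$tol_n) "OK" else "FAIL"))
  invisible(x)
}

#' Write a runnable configuration directory
#'
#' Writes `weather.csv` and `config.yaml` for a [sim_config()] such that
#' [read_config()] reproduces the run. Soil layers and scalar cultivar
#' overrides are written explicitly; cultivar table parameters are carried by
#' the package defaults (sufficient for the generated scenario families).
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created)
#' @return the config file path, invisibly
#' @export
write_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_weather(cfg$weather, file.path(dir, "weather.csv"))
  prof <- cfg$profile
  soil <- list(thickness = prof$thickness, clay = prof$clay, sand = prof$sand,
               bd = prof$bd, ph = prof$ph, wcst = prof$wcst, wcfc = prof$wcfc,
               wcwp = prof$wcwp, theta = prof$theta,
               fom_c = prof$fom_c, fom_n = prof$fom_n,
               hum_c = prof$hum_c, hum_n = prof$hum_n,
               urea_n = prof$urea_n, nh4_n = prof$nh4_n, no3_n = prof$no3_n,
               standing_water = attr(prof, "standing_water"),
               residue_mass = attr(prof, "residue_mass"),
               residue_cn = attr(prof, "residue_cn"),
               drain_frac = attr(prof, "drain_frac"),
               perc_cap = attr(prof, "perc_cap"),
               bund = attr(prof, "bund"))
  defaults <- cultivar_params()
  cult <- cfg$cultivar
  over <- list()
  for (nm in names(defaults)) {
    if (is.numeric(cult[[nm]]) && length(cult[[nm]]) == 1 &&
        !identical(cult[[nm]], defaults[[nm]])) {
      over[[nm]] <- cult[[nm]]
    }
  }
  m <- cfg$management
  mgmt <- list(establishment = m$establishment,
               irrigation = m$irrigation,
               residue_in = m$residue_in)
  if (!is.null(m$irrigation$events)) {
    mgmt$irrigation$events <- as.list(m$irrigation$events)
  }
  if (nrow(m$n_events)) mgmt$n_events <- as.list(m$n_events)
  y <- list(weather = "weather.csv", soil = soil, cultivar = over,
            management = mgmt, seed = cfg$seed,
            substeps_heat = cfg$substeps_heat)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(y, path)
  invisible(path)
}
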