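## small fixtures shared across tests, built in code

two_layer_profile <- function(theta = 0.38, ...) {
  soil_profile(thickness = c(0.1, 0.1), clay = 0.3, sand = 0.3, bd = 1.3,
               ph = 6.5, wcst = 0.50, wcfc = 0.38, wcwp = 0.18,
               theta = theta, ...)
}

## a single soil layer as a plain list, for the per-layer C/N operations
one_layer <- function(urea_n = 0, nh4_n = 0, no3_n = 0, fom_c = 0,
                      fom_n = 0, hum_c = 0, hum_n = 0) {
  list(urea_n = urea_n, nh4_n = nh4_n, no3_n = no3_n, fom_c = fom_c,
       fom_n = fom_n, hum_c = hum_c, hum_n = hum_n)
}

constant_weather <- function(days, tmin = 22, tmax = 30, srad = 18, rain = 0) {
  data.frame(date = as.Date("2020-06-01") + seq_len(days) - 1,
             tmin = tmin, tmax = tmax, srad = srad, rain = rain)
}
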