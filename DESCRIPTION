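Package: paddysim
Title: Process-Based Simulation of Rice Growth Under Drought and Nitrogen Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-time-step, layered-soil, process-based simulator of paddy and
    aerobic rice growth. Couples one-dimensional soil heat conduction, soil carbon
    and nitrogen pool turnover (mineralization, urea hydrolysis, nitrification,
    denitrification, ammonia volatilization, leaching), a tipping-bucket soil water
    balance with matric-potential based alternate wetting and drying irrigation,
    root-front extension and layer-wise root distribution, coupled mass-flow plus
    diffusion nitrogen uptake, and drought (Sw) and nitrogen (SN) stress indices
    that scale radiation-use-efficiency based growth and shift assimilate
    allocation. Includes seeded synthetic weather and scenario generators for
    water-management, nitrogen-split, aerobic, and multi-variety drought designs,
    and the standard crop-model evaluation statistics (regression, normalized RMSE,
    model efficiency, Welch t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
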