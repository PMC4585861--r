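Package: ecoclimex
Title: Mechanistic Ecoclimatic Suitability Modelling on Gridded Climatologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A process-oriented climatic niche model for perennial tropical
    crops in the CLIMEX tradition. Monthly climatologies (minimum and maximum
    temperature, precipitation, morning and afternoon relative humidity) are
    interpolated to 52 weekly series, passed through a single-bucket soil
    moisture water balance, and combined into weekly temperature and moisture
    growth indices, four annual stress accumulators (cold, heat, dry, wet), a
    degree-day establishment gate, and an annual Ecoclimatic Index (EI) scaled
    0-100. Includes the published oil palm (Elaeis guineensis) parameter set,
    suitability classification with per-class area accounting on geographic
    grids, climate-scenario perturbation and comparison (stress-change and
    class-transition maps), occurrence-point overlay validation, and a
    seeded synthetic-climatology generator so the full pipeline is testable
    without external data downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
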