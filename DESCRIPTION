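Package: dvmloss
Title: Dinoflagellate Vertical Migration and Subeuphotic Nitrate Loss from
    Profiler Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting dinoflagellate diel vertical migration in
    moored-profiler (e.g. Wirewalker) depth-time records and for quantifying
    the biologically driven nitrate loss it causes below the euphotic zone.
    Fields are remapped from depth to isopycnal coordinates to remove
    internal-wave heaving, water masses are tracked on isopycnals by their
    spice (temperature-salinity) signature, and nitrate-specific rates of
    change are estimated from exponential fits to nitrate observations at
    water-mass reappearances. Rates are gridded, integrated into cumulative
    loss fields with first-order error propagation, and compared against a
    nitrate-temperature climatology. Includes a synthetic-ocean generator
    with recorded ground truth (internal waves, along-isopycnal advection,
    light-triggered migration, prescribed uptake, sensor noise) for
    validating every stage, plus sensor preprocessing (nitrate quality
    control, fluorescence quenching correction, PAR, euphotic depth,
    turbidity) and bloom diagnostics (descent speed, loss-biomass
    correlation, N:Chl ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    ncdf4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
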