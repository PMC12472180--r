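Package: dielpond
Title: Diel Biogeochemistry of Shallow High-Altitude Ponds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for diel (dawn-to-dusk) biogeochemical studies
    of shallow ponds: Beer-Lambert fitting of the diffuse PAR attenuation
    coefficient from depth-irradiance profiles, PAM chlorophyll-fluorescence
    photophysiology indices (effective and maximal quantum yield, relative
    electron transport rate) with midday photoinhibition and recovery
    summaries, headspace-equilibration back-calculation of dissolved CO2, CH4
    and N2O with altitude-aware percent saturation and floating-chamber flux
    estimation, endpoint nutrient rates of change with inhibitor-difference
    partitioning of nitrification into bacterial, archaeal and other-process
    contributions, a parametric-versus-nonparametric decision tree for
    morning-versus-afternoon contrasts plus Spearman correlation screening,
    and a seeded synthetic-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
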