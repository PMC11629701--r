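Package: virovory
Title: Food-Web Modelling and Single-Cell Isotope Tracing of Viral Carbon and Nitrogen Consumption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying consumption of virus particles by
    marine bacteria and phagotrophic protists (virovory). Implements a
    three-compartment virus-bacteria-grazer ordinary differential equation
    food-web model with equilibrium spin-up and simulated filtration
    treatments; conversions from nanoSIMS secondary-ion ratios to isotope atom
    fractions, atom percent excess and substrate-derived biomass fractions
    (X_net) with implied cell-division counts; processing of multi-cycle
    ion-count image stacks into per-region-of-interest isotope statistics
    (cycle alignment, dead-time correction, particle thresholding, hotspot
    finding); removal-rate statistics for flow-cytometry abundance time
    series; and seeded synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
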