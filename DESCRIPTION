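Package: warmsoil
Title: Soil CO2 Efflux, Carbon Stocks, and Radiocarbon Age Modelling for
    Paired-Plot Soil-Warming Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational chain for long-term paired-plot soil-warming
    experiments: static-chamber CO2 flux calculation, Gaussian
    temperature-response modelling with gap-filled soil temperatures and
    annual upscaling (by model and by interpolation), a per-degree
    warming-response statistic with its filtering rules, soil organic
    carbon stock accounting with an equivalent-mass compaction
    correction, dissolved organic carbon fluxes, a heterotrophic carbon
    budget closure, and a three-pool steady-state radiocarbon
    compartment model yielding carbon age, transit-time, and Delta-14C
    mass distributions. A synthetic-data module emulates the statistical
    structure of such experiments so the full pipeline runs and is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
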