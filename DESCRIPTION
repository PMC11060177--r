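Package: h2sink
Title: Microbial Hydrogen Sinks in Sand-Bentonite Backfill: Reactor
    Simulation, Sulfate-Reduction Rates, and Spatial Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of flow-through sand-bentonite reactor
    experiments probing microbial hydrogen sinks in deep geological
    repository backfill. Provides a forward biogeochemical simulator
    (hydrogenotrophic sulfate reduction, gypsum dissolution, iron-sulfide
    precipitation, sulfate-gated methanogenesis) with a replicate
    observation sampler and a spatial amplicon sequence variant (ASV) grid
    generator; sulfate-reduction rate estimators by zero-order linear
    regression and by global mass balance over the water, gypsum and
    outflow budgets; electron donor/acceptor supply ledgers,
    stoichiometric hydrogen-oxidation conversion, iron-to-sulfur mineral
    ratio classification, and repository-scale hydrogen-sink
    extrapolation; and kitome-corrected relative abundance, presence
    confirmation, Hellinger ordination, and spatial biomass statistics on
    a 5x7 sampling grid.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
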