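Package: metanest
Title: Meta-Ecosystem Dynamics on Spatially Nested Topologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of four-patch meta-ecosystems in which
    nutrient-producer-consumer food chains are coupled by inorganic resource
    flows between nearby ecosystems of different types and by consumer
    dispersal between distant ecosystems of the same type. Provides
    connectivity-matrix topology builders (spatially nested and fully
    connected resource-flow control), seeded initial-condition ensembles,
    long-run attractor classification (equilibrium versus oscillation,
    spatially homogeneous versus heterogeneous, bistability detection),
    emergent source-sink and trophic-regulation metrics, local and
    meta-ecosystem function summaries, and sweep pipelines for state
    diagrams, bifurcation transects and dispersal planes.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
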