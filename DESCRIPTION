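Package: geosminR
Title: Quantification and Source Apportionment of Geosmin-Producing
    Bacteria in the Fish Biosphere
Version: 0.1.0
Authors@R:
    person("Aqua", "Methods", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for locating and apportioning microbial geosmin
    production across the compartments of a fish-farm biosphere (cage
    water, intestinal mucous, digesta, dorsal-fin surface). Implements
    absolute qPCR quantification of the geosmin synthase gene geoA (four
    group assays summed) and total bacterial 16S rRNA genes with
    standard-curve QC gates; a producer-to-total-bacteria census with
    one-way ANOVA/Tukey comparison of intestinal sections; taxonomic
    screening of OTU tables for putative geosmin-producer clades together
    with top-taxa aggregation and Chao1 richness; constrained ordination
    (redundancy analysis) of community composition against geosmin and
    geoA levels; and a per-cell-yield compartmental mass balance that
    estimates how much flesh geosmin intestinal bacteria could supply,
    with delta-method uncertainty propagation. A seeded forward simulator
    generates complete synthetic datasets with known ground truth so that
    every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
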