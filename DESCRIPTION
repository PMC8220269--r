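Package: MediaGA
Title: Genetic-Algorithm Design of Growth Media for Microbial Communities
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Search for nutrient combinations (growth-medium compositions)
    that drive a multispecies microbial community toward a target phenotype.
    Provides an elitist genetic algorithm over combinatorial environment
    spaces, a seedable Monod consumer-resource community simulator with
    cross-feeding, auxotrophies and a death rate, community-level phenotype
    metrics (Shannon entropy, species richness, metabolic-exchange counts,
    secretion and directed-flux totals), six objective families including
    target taxonomic compositions, and benchmarking machinery (generations to
    the 99th percentile, final percentile, performance score, crossover and
    mutation probability grid search, random-search baseline) against
    exhaustively enumerated environment-phenotype mappings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'MediaGA-package.R'
    'nutrient-pool.R'
    'env-space.R'
    'medium.R'
    'metrics.R'
    'community.R'
    'simulate.R'
    'mapping.R'
    'objectives.R'
    'ga.R'
    'benchmark.R'
    'random-community.R'
    'fixture.R'
    'config-run.R'
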