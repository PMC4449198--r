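Package: aviqtl
Title: QTL and Expression-QTL Mapping for Avian Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Avian", "Genomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Haley-Knott regression QTL and eQTL mapping for two-line
    advanced intercrosses: conditional genotype probabilities from a
    hidden Markov model over the genetic map, single- and two-locus
    genome scans with covariates, permutation-based genome-wide
    significance thresholds, 1.8-LOD-drop support intervals,
    local (cis) versus distal (trans) eQTL classification with a
    dual-threshold permutation scheme, candidate quantitative-trait-gene
    prioritisation by QTL-eQTL interval overlap plus expression-trait
    association, and trans-eQTL hotspot detection against a
    uniform-placement coverage null. Includes a full synthetic-data
    generator for an F8 advanced intercross (genotypes, covariates,
    traits with additive, dominance and epistatic architecture, and
    expression with cis effects, trans hotspots and expression-mediated
    trait effects) so the entire pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
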