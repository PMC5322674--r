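Package: pedwgs
Title: Pedigree-Aware Analysis of Whole-Genome Sequencing Variants
Version: 1.0.0
Authors@R:
    person("Pedigree WGS Toolkit Developers", role = c("aut", "cre"),
           email = "pedwgs@example.org")
Description: Tools for family-based interpretation of whole-genome sequencing
    data: simulation of multi-generation pedigrees with planted copy-number
    deletions and genotyping error, read-depth based detection of heterozygous
    deletions from binned coverage tracks, inference of the parental origin of
    a hemizygous deletion from Mendelian-inconsistency informative sites,
    partitioning of variants by disease inheritance model with a population
    frequency / deleteriousness / evidence filtering cascade, and phenotype
    driven prioritization of candidate genes and copy-number intervals against
    a Human Phenotype Ontology term set, including confidence tiers and exact
    term-subset robustness analysis.
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
    VariantAnnotation
Config/testthat/edition: 3
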