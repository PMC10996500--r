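Package: pedforge
Title: Forward Simulation of Family Pedigrees, Gene-Drop Genomes and
    Pedigree Relationship Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of family-pedigree structures with
    generation-varying sibship-size distributions, simulation of
    misattributed-paternity events, native gene-drop simulation of diploid
    genomes onto arbitrary fixed pedigrees (with founder identification and
    generation-tick inference), quantification of pairwise genetic
    relationships by meiotic distance, generation depth difference and
    relationship type, path-counting expected kinship, and a beta
    allele-sharing kinship estimator for validating simulated genomes
    against pedigree expectations. Pedigrees are represented as directed
    acyclic graphs and read and written in edge-list (.nx), PLINK .ped/.fam
    and generation-ordered four-column formats; genomes are exchanged as
    phased VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
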