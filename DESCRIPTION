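Package: kinnet
Title: Kinship Networks, Parentage and Inbreeding for Small Microsatellite-Typed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising small wild populations genotyped at
    codominant microsatellite loci: marker quality control (allele
    frequencies, heterozygosities, exact Hardy-Weinberg and linkage
    disequilibrium tests, null-allele diagnostics, duplicate-genotype
    screening), maximum-likelihood pairwise relatedness over the Cotterman
    k-coefficient simplex with relationship classification, first-order
    genetic-network construction and permutation tests of group
    relatedness, likelihood-based parentage assignment with simulated
    confidence thresholds, full-likelihood sibship reconstruction with
    parental-genotype inference and breeder counting, internal-relatedness
    inbreeding assessment against a random-mating Monte Carlo null, and a
    ground-truthed pedigree simulator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
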