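Package: lcrelate
Title: Pairwise Relatedness Estimation from Ultra-Low-Coverage Pseudo-Haploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates 1st- and 2nd-degree genetic relatedness between
    individuals sequenced at very low coverage, as is typical for ancient DNA
    shotgun screening. Performs random pseudo-haploid genotype calling from
    samtools mpileup text restricted to a biallelic allele-frequency panel,
    computes the pairwise Queller-Goodnight relatedness estimator on the
    halved-relatedness-coefficient (HRC) scale, classifies pairs by hard
    thresholds at the class mid-points, and calibrates class distributions,
    false-positive rates and posterior probabilities by Monte-Carlo simulation
    of pseudo-haploid pairs at fixed identity-by-descent sharing. Includes
    PLINK text (.ped/.map, .tped/.tfam, .frq) readers and writers and a
    synthetic-fixture generator for panels, pedigreed cohorts and pileups.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
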