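Package: snppop
Title: Population Diversity Analysis for Multi-Breed SNP-Array Panels
Version: 0.1.0
Authors@R: person("snppop", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality control and population-genetic diversity analysis for
    diploid biallelic SNP-array genotypes in PLINK text PED/MAP format.
    Implements per-breed observed and unbiased expected heterozygosity,
    Weir-Cockerham F-statistics (within-population Fis and pairwise Fst),
    Wright's island-model gene-flow transform Nm = (1 - Fst)/(4 Fst),
    allele-sharing distances between individuals with a from-scratch
    neighbour-joining tree serialized as Newick, and genotype principal
    component analysis with Patterson normalization. Includes a
    Balding-Nichols simulator of multi-population SNP panels with known
    differentiation, inbreeding and missingness so the whole pipeline is
    testable against parameter-recovery truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
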