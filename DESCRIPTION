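Package: breedpanel
Title: Breed-Informative SNP Panels from Multi-Breed Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic workup of multi-breed SNP genotype data:
    PLINK text and VCF input with quality control (call rate, minor allele
    frequency, identity-by-state pruning); within-population diversity
    (observed and expected heterozygosity, fixation index, Hill-number
    diversity profiles); exact Hardy-Weinberg equilibrium tests with
    ternary-plot coordinates; pairwise population differentiation
    (Weir-Cockerham F_ST, Nei G_ST, Euclidean distance) and a chi-square
    based F_ST-outlier scan; and discriminant analysis of principal
    components (DAPC) for selecting breed-informative SNP panels and
    comparing full- versus reduced-panel breed assignment. Includes a
    Balding-Nichols simulator of multi-breed genotype datasets for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
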