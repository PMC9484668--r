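Package: CarrierFreq
Title: Carrier Prevalence of Putatively Pathogenic Gene Variants Under
    Hardy-Weinberg Equilibrium
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates heterozygous, homozygous and compound-heterozygous
    carrier prevalence for rare recessive gene variants from population
    allele-count tables of the kind exported from gnomAD. Variants are
    classified as putatively pathogenic by a k-of-n consensus over
    categorical in silico predictor calls (SIFT, PolyPhen2,
    MutationTaster2021, FATHMM-MKL, PROVEAN), optionally extended by
    high-confidence loss-of-function annotation and literature evidence.
    Prevalence components (2pq, q-squared, sum of squared per-variant
    frequencies, and the compound-heterozygote remainder) are computed per
    population and sex stratum under Hardy-Weinberg equilibrium. A
    synthetic-cohort simulator with known ground truth supports end-to-end
    validation, including genotype-level simulation and Wahlund-structured
    cohorts for the Hardy-Weinberg consistency check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
biocViews: Genetics, VariantAnnotation, Software, PopulationGenetics
RoxygenNote: 7.3.3
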