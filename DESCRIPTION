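Package: pollenkin
Title: Paternity Analysis, Pollen Dispersal Kernels and Fine-Scale
    Spatial Genetic Structure from Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the pollination genetics of spatially mapped plant
    populations genotyped at codominant microsatellite loci. Implements
    likelihood-based paternity assignment with simulation-calibrated LOD
    thresholds and pollen-immigration bounds; direct and indirect
    (correlated-paternity decay) estimation of power-exponential pollen
    dispersal kernels; a Bayesian spatially explicit mating model with
    male fecundity random effects fitted by Markov chain Monte Carlo;
    mixed-mating-system estimation (multilocus and single-locus
    outcrossing rates, correlated paternity, effective number of pollen
    donors); genetic diversity summaries, Hardy-Weinberg exact tests and
    null-allele estimation; and fine-scale spatial genetic structure
    analysis (Loiselle kinship, permutation-tested log-distance
    regression, correlograms and the Sp statistic). A synthetic-data
    generator with a known mating model and truth ledger supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
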