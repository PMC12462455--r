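Package: paleoibd
Title: Identity-by-Descent Sharing Analyses for Ancient DNA Cohorts
Version: 0.1.0
Authors@R:
    person("paleoibd", "developers", email = "paleoibd@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing identity-by-descent (IBD) segment sharing
    among low-coverage ancient genomes. Reads and filters IBD segment tables
    (ancIBD-style output), builds symmetric pairwise total-IBD matrices, and
    implements permutation tests that distinguish population replacement from
    cultural diffusion: a label-shuffle test on within- versus between-group
    sharing, a column-permutation test for local genetic continuity, and an
    exhaustive row-permutation test of differential group contribution.
    Also provides geographic/mortuary proximity contrasts with exact and
    tie-corrected Wilcoxon rank-sum tests, kinship estimation from pairwise
    mismatch rates of pseudo-haploid genotypes, a pedigree IBD simulator
    (gene dropping with crossover interference) that builds relationship
    envelopes for degree classification, a sex-biased-admixture Z statistic,
    and a fully seeded synthetic cohort generator for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
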