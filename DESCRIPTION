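Package: finescale
Title: Fine-Scale Within-Country Ancestry Estimation from Haplotype Copying Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for fine-scale, within-country genetic ancestry
    estimation and its temporal analysis. Builds geographically anchored
    reference groups from phased haplotype data via spatial thinning and an
    iterative identity-proportion selection procedure, profiles individual
    ancestry with a haplotype-copying (Li-Stephens) painter and
    simplex-constrained mixture estimation, validates identifiability with
    pedigree recombination simulations, and tracks birth-year-stratified
    ancestry change with local regression curves, entropy-based heterogeneity
    trends, inbreeding averages, Hudson F_ST, and distance-weighted municipal
    ancestry profiles. Includes a synthetic-data generator (Balding-Nichols
    founders recombined through simulated meioses) so the whole workflow runs
    and is verified at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
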