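Package: phagedefense
Title: Antiphage Defense System Content and Phage Resistance Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the antiphage defense-system content of
    bacterial genomes to their phenotypic phage resistance. Ingests
    PADLOC-dialect defense-system annotation tables, canonicalizes system
    names (grouping subtypes) and assigns mechanism categories, models
    strains-by-phages host-range matrices with explicit tested/untested
    state, computes per-strain susceptibility percentages and
    max-normalized efficiency of plating (EOP), partitions strains into
    rank-based susceptibility groups, classifies per-system prevalence in
    resistant versus susceptible strains, and correlates defense-system
    burden with susceptibility. Includes a calibrated synthetic
    strain-phage panel generator with known ground truth for end-to-end
    validation, and a pipeline runner that emits the analysis tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
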