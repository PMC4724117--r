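Package: paralogdiv
Title: Divergence and Importance of Small-Scale Versus Whole-Genome Gene
    Duplicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares paralog pairs arising from small-scale duplication
    (SSD) with ohnolog pairs retained from whole-genome duplication (WGD):
    shared Gene Ontology annotation (Dice) similarity for the biological
    process, molecular function and cellular component domains, tissue
    expression-profile correlation, ortholog-based evolutionary rates (dN
    and dN/dS with a dS saturation filter), multifunctionality, and
    essentiality/disease enrichment, all stratified by dN bins and compared
    with two-tailed Mann-Whitney U tests and pooled two-proportion Z tests.
    Ships a seeded synthetic-data generator that emulates the joint
    statistical structure of the input tables so the full pipeline is
    testable without database extractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
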