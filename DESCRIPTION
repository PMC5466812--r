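Package: ecophylo
Title: Ecophylogenetic Analysis of Paired DNA/RNA Amplicon Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecophylogenetic analysis of microbial communities
    observed in paired DNA and RNA amplicon fractions. Provides Hill-number
    and Chao1 alpha diversity, Bray-Curtis dissimilarity with square-root and
    Wisconsin double standardization, core-microbiome resampling curves, the
    per-OTU mean expression ratio (a relative-activity trait derived from
    RNA:DNA relative abundances) with standard errors, standardized effect
    sizes of mean pairwise and mean nearest taxon distances under a
    tip-shuffle null model, and Blomberg's K phylogenetic signal including a
    measurement-error variant (Kse). A synthetic-data generator produces
    trees, tree-structured traits, community memberships and paired count
    tables so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
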