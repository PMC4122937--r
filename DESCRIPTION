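Package: nanoterm
Title: Telomere-Aware Finishing and Analysis of Nanochromosomal Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and analysing the highly fragmented,
    telomere-capped "nanochromosome" genomes of stichotrichous ciliate
    macronuclei. Implements telomere detection and contig classification,
    a deterministic paired-end read mapper with explicit mismatch budgets,
    pair-constrained contig end extension toward telomere completion with
    greedy overlap merging and chaff removal, telomere-addition-site
    (alternative fragmentation) calling from telomere-stripped reads,
    read-depth chromosome copy-number estimation with cross-library
    normalization, assembly metrics, and two-gene synteny statistics.
    Includes a synthetic nanochromosomal genome and paired-end read
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
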