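Package: codonopt
Title: Codon Optimization and Expression Diagnostics for Heterologous
    Genes in Candida albicans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating codon-optimized coding
    sequences for heterologous expression in Candida albicans and other
    CTG-clade yeasts. Builds codon usage tables (including CountCodon-style
    tabulation from a gene set), generates coding-sequence variants under
    five optimization strategies (threshold-random, guided-random with
    entire-genome or highly-expressed-gene tables, bulk maximal-CAI, and
    scaffold mutation transfer), computes per-variant sequence diagnostics
    (codon adaptation index, GC content, rare-codon runs, minimum-free-energy
    folding score of the full coding region and its 5' region), and analyses
    replicate flow-cytometry brightness measurements (autofluorescence
    correction, normalization to the brightest variant, one-way ANOVA with
    Tukey contrasts, and brightness-versus-parameter association). A
    synthetic-data module generates usage tables, gene sets, proteins and
    replicate brightness with a folding-linked expression model so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
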