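Package: podevol
Title: Fixation Analysis for Serial-Passage Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing allele fixations in long-term serial-passage
    evolution experiments on clonal populations, modelled on submerged
    cultivation of filamentous fungi. Implements fixation filtering
    (coverage/frequency, founder support, multi-population sharing,
    low-complexity masks, dinucleotide adjacency), timepoint reconciliation
    against validation data, variant effect classification on GFF3 gene
    models, trinucleotide-context-matched permutation nulls for
    protein-altering excess and gene-level parallelism, ortholog conservation
    enrichment tests with Miyata physicochemical distances, and headline
    evolutionary statistics (transition shares, Nei-Gojobori dN/dS, fixation
    accumulation regression, mutator homogeneity). Includes a synthetic
    serial-passage experiment generator with a ground-truth ledger so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
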