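Package: homeoprot
Title: Homolog Abundance Patterns in Allotetraploid Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein abundance patterns of paralogs and
    homeologs in allotetraploid proteomes. Pairs homologous proteins from
    alignment statistics (coverage, identity and E-value filters followed by
    reciprocal best hits), calls differentially abundant proteins between two
    tissues from replicated quantification matrices, classifies homeolog
    abundance bias between sub-genomes and paralog abundance divergence,
    categorises pairs by how many copies respond between tissues, estimates
    Ka/Ks by Nei-Gojobori counting on back-translated codon alignments with
    selection classification, correlates evolutionary rate with abundance,
    and performs Fisher term enrichment. A synthetic-data generator produces
    allotetraploid proteome fixtures (gene families with one copy per
    sub-genome plus within-sub-genome paralogs, codon pairs diverged at a
    controlled dN/dS, replicated two-tissue quantification with lognormal
    noise and random missingness) together with the ground truth needed for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
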