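Package: frtscan
Title: Genome-Wide Discovery and Classification of FRT-Like Recombination Sites
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans genomic DNA for FRT-like sequences, the degenerate
    pseudo-sites that evolved Flp recombinase variants can use as
    recombination targets. A rule-based sliding-window scanner evaluates
    every 34-nt window against an experimentally derived consensus model
    (spacer composition, proximal-8 match rules, binding-element match and
    run requirements, homopolymer filter), partitions hits into unique and
    exactly-duplicated pools across both strands, assigns each site to a
    class and canonical numeric proximal-8 subclass, groups sites with
    orientation-independent identical spacers, and ranks candidate
    counter-selection targets by positionwise sequence identity. Includes
    a seeded synthetic-genome generator with planted sites and repeat
    families for fully reproducible ground-truth testing.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
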