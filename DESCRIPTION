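Package: sexmarkr
Title: High-Throughput Discovery of Sex-Specific Indel Markers from
    Male and Female Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers PCR-ready sex-diagnostic markers by bidirectional
    whole-genome comparison of a male and a female assembly. Catalogs large
    (>100 bp) insertion/deletion variants from unique k-mer anchor chains,
    classifies them into genomic functional regions and repeat classes, ranks
    deletion markers by long-read depth with trough-based tiering, designs
    primer pairs for variant target regions in bulk using nearest-neighbor
    melting temperatures, screens them by electronic PCR for single-band
    amplicons, and predicts per-sex gel band patterns (two bands in the
    heterogametic sex, one in the homogametic sex). Includes a synthetic
    diploid-sex genome-pair generator with known truth so the whole pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
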