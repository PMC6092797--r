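Package: clipmap
Title: Cell Type-Specific CLIP Analysis of Differential RNA Binding and
    Splicing Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparing HITS-CLIP protein-RNA
    binding profiles between a cell type-specific library and its whole-tissue
    reference. Covers reverse-transcription artifact filtering, per-gene peak
    calling against a uniform-coverage null, joint-peak definition over pooled
    conditions, site-wise differential binding by Fisher's exact test on
    relative peak heights, positional motif (YCAY, polypyrimidine, U-rich
    tetramer) and conservation profiles, junction-based differential cassette
    exon and alternative last exon usage, and position-dependent predictions
    of splicing direction from binding changes (the RNA map), with a fully
    seeded synthetic-data generator that emulates the unequal replicate and
    depth design of motoneuron versus whole-spinal-cord CLIP for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
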