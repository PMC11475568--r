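Package: hemescan
Title: Homology-Independent Detection of Multi-Heme Cytochrome Gene Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans annotated prokaryotic genomes for candidate extracellular
    electron transfer (EET) machinery without relying on homology. Counts
    c-type heme-binding motifs (CXXCH and spacing variants) per protein,
    classifies protein localization with a transparent hydropathy heuristic or
    external Phobius predictions, assembles contig-local gene neighborhoods
    around exported multi-heme cytochromes, and applies three inclusion
    criteria (an exported MHC, a heme-rich >= 4-heme MHC, and >= 15 hemes in
    the cluster). Also flags type IV aromatic pilin candidates, clusters
    discovered MHCs into protein families with gap-masked alignments ready for
    profile-HMM building, and generates fully determined synthetic assemblies
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
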