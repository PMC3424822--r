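Package: estclean
Title: Pattern Analysis and Cleanup of Raw Sanger EST Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cDNA terminal structures (adapters, restriction enzyme
    recognition sites, poly(A)/poly(T) tails and cloning-vector borders) in raw
    Sanger expressed sequence tag (EST) reads, scores each detected terminus
    with a weighted completeness/context/match confidence score, classifies
    library-construction artifacts such as restriction enzyme cutting
    abnormalities (RECA) and double-termini adapter (DBT) chimeras from the
    read's terminus pattern, and extracts the bona fide cDNA insert by
    quality- and vector-aware trimming between the best reasonable terminus
    pair. Ships the classic EcoRI/XhoI directional-cloning protocol as a
    default and includes a synthetic raw-read generator with full ground truth
    for every supported construct layout, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
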