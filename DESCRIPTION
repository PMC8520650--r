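Package: phosflow
Title: Isobaric-Label Phosphoproteomics Quantification and Kinase Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies isobaric-label (iTRAQ/TMT) phosphoproteomics experiments
    from peptide-spectrum-match (PSM) reporter intensities: sum-of-intensities
    channel normalization, log2 ratios against a denominator channel,
    intensity-ranked z-scores, PSM-count-weighted aggregation to phosphosite,
    phosphopeptide and protein levels, and tiered significance/regulation calls.
    Downstream kinase inference includes NSAF relative protein abundance, a
    regulatory-site-weighted kinase activity score, motif-x-style binomial motif
    enrichment over 15-residue sequence windows, and kinase-family substrate
    percentages. A seeded synthetic-data generator emulates 4-plex duplicate
    labelling experiments with planted fold changes, sequence motifs and kinase
    activity shifts so every stage is testable by parameter recovery.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
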