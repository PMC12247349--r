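Package: ap2erf
Title: Genome-Wide Identification and Evolutionary Analysis of AP2/ERF
    Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for genome-wide
    characterization of the AP2/ERF transcription-factor superfamily:
    profile-domain-hit-based family identification with a
    longest-isoform rule, subfamily classification (AP2, ERF, RAV,
    Soloist) from domain architecture with tree-based refinement,
    neighbor-joining phylogeny under a p-distance model with partial
    deletion, tandem/segmental/homoeolog duplicate-pair classification
    for diploid and allotetraploid genomes, Nei-Gojobori (1986) Ka/Ks
    estimation with Jukes-Cantor correction and Fisher's exact
    significance test, and CPM-based expression summarization.  A
    synthetic-genome generator plants gene families, duplication events
    and expression signal with full ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    seqinr,
    withr
Config/testthat/edition: 3
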