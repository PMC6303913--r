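Package: selexr
Title: SELEX-Seq K-Mer Relative Affinity Analysis with Markov Background
    Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of SELEX-seq (systematic evolution of ligands by
    exponential enrichment followed by deep sequencing) experiments for
    DNA-binding proteins such as MADS-domain transcription-factor dimers.
    Provides per-round k-mer counting of randomized-library reads, a
    sixth-order Markov background model of the unselected Round-0 library,
    per-k-mer relative affinity estimation as the enrichment of final-round
    k-mer frequencies over the model-implied background, CArG-box prevalence
    statistics, cross-condition affinity comparison, selection of top-affinity
    k-mers with their most recurrent bound sequences, and anchored
    position-frequency-matrix motif construction with MEME-minimal and JASPAR
    export. A synthetic SELEX round generator with a known affinity landscape
    supports end-to-end parameter-recovery validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
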