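Package: ittscan
Title: Intrinsic Transcription Termination Site Inference from Bacterial RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers intrinsic (rho-independent) transcription termination sites
    in bacterial genomes by combining strand-specific RNA-seq read depth with
    hairpin prediction in inter-operonic regions (IRs). Cumulative read-depth
    curves are differenced over a sliding window (sl1) and differenced again
    (sl2) to locate the first positive-slope region after the post-stop-codon
    coverage drop; the IR is segmented into three zones around it. Candidate
    stem-loop hairpins are enumerated as perfect inverted repeats downstream of
    the stop codon, scored with an additive nearest-neighbor style free-energy
    model, grouped into cluster (inter-hairpin gap < 15 nt) or single
    termination units, and the unit nearest the stop codon (identified) is
    matched against the unit nearest the positive-slope start (RNA-seq
    derived). Poly-U/A trails downstream of hairpins are searched with a
    mismatch-tolerant scanner. A seeded synthetic-data generator emits genomes,
    annotations and depth tracks with planted terminators so the whole pipeline
    is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
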