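Package: termwindow
Title: Termination-Window Analysis of RNA Polymerase II Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing RNA polymerase II occupancy around
    transcription terminators in budding yeast. Classifies transcription
    units (snoRNA, CUTs, SUTs, XUTs, attenuated and ordinary protein-coding
    genes) as termination-defective in mutant-versus-wild-type contrasts via
    a readthrough index, builds anchored metagene profiles and heat maps,
    localises factor recruitment peaks (Nrd1, Pcf11) and tests positional
    shifts by paired sign-flip permutation, computes set-overlap and
    proportion statistics, and quantifies amplicon-level ChIP/DIP fold
    enrichment. A mechanistic elongation-termination simulator (per-nt
    termination hazards, survival x dwell occupancy, Poisson counts)
    generates coverage tracks with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
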