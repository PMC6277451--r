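Package: chromalib
Title: Peptide-Centric Search, Validation and Quantification for
    Data-Independent Acquisition Proteomics with Chromatogram Libraries
Version: 0.1.0
Authors@R:
    person("chromalib", "developers", email = "chromalib@example.org",
           role = c("aut", "cre"))
Description: A peptide-centric analysis engine for data-independent
    acquisition (DIA) mass spectrometry. Demultiplexes 50%-overlapped
    isolation-window schemes into half-width pseudo-spectra, scores
    spectrum- or chromatogram-library peptides against DIA runs with a
    weighted dot-product primary score plus auxiliary match features,
    calibrates retention time with a non-parametric kernel-density ridge
    and a Gaussian/uniform mixture model, controls peptide and protein
    false discovery rates by semi-supervised target-decoy re-scoring,
    builds DIA-derived chromatogram libraries from narrow-window
    gas-phase-fractionated runs, and produces interference-screened
    fragment-ion quantities aggregated to peptides and proteins.
    Includes a fully ground-truthed synthetic-data generator (libraries,
    runs, multi-run studies written as mzML) used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    DBI,
    RSQLite,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
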