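Package: gdip
Title: GPCR-Drug Interaction Prediction from Fingerprint Spectra and Grey
    Pseudo Amino Acid Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of interactions between G-protein-coupled
    receptors (GPCRs) and drug compounds. Drugs are encoded as the discrete
    Fourier amplitude spectrum of their 256-digit path-based molecular
    fingerprint; receptor sequences are encoded as a 22-component pseudo amino
    acid composition whose sequence-order terms come from a GM(1,1) grey model
    fitted to the mean-polarity profile of the sequence. The two blocks are
    fused into a weighted 278-component pair vector and classified with a fuzzy
    K-nearest-neighbour rule. Includes leave-one-out (jackknife) evaluation,
    (K, m) grid search, a seeded synthetic benchmark generator, and readers for
    pair tables, FASTA sequences and fingerprint tables.
License: MIT
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
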