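Package: g4cr
Title: G-Quadruplex-Containing Regions and Their Structural Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies G-quadruplex-containing regions (G4CRs) in DNA
    sequences by exhaustively enumerating every stable three-tetrad
    quadruplex isomer (G-register, spare-tire and single-bulge variants)
    under an empirical melting-temperature model, and quantifies structural
    polymorphism per region: total isomer count (N_tot), maximum number of
    simultaneously folded tandem quadruplexes (N_tand), and per-guanine
    folding multiplicity. Includes promoter-window extraction around
    transcription start sites, quantile-classified positional density
    profiles, enrichment ratios, mononucleotide shuffle nulls, a synthetic
    sequence generator, and an independent brute-force enumerator used as a
    correctness oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
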