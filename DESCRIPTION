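Package: saponinMS
Title: In-Silico Fragmentation and MS/MS Annotation of Sea Cucumber
    Triterpene Glycosides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating negative-mode tandem mass spectra of
    (poly)sulfated triterpene glycosides (saponins) from sea cucumbers.
    Implements glycosidic-bond fragment ladder generation (Domon-Costello
    Y/B/C/Z ions) with sodium-salt adduct handling for polysulfated
    compounds, a rule engine that infers sulfation state, glycan sequence,
    aglycon features and side-chain class from diagnostic neutral losses,
    spectral-library search with cosine scoring and retention-time
    confirmation, molecular-network construction with modified-cosine
    similarity, and a synthetic structure/spectrum generator for testing.
    All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
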