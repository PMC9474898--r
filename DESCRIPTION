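Package: emtlnc
Title: EMT Scoring and lncRNA Signature Analysis for Tumor Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives marker-anchored long non-coding RNA (lncRNA) signatures of
    epithelial-mesenchymal transition (EMT) from expression matrices, computes a
    weighted EMT score (including the published 15-coefficient signature shipped
    as a fixture), classifies samples and cohorts into EMT classes, and runs the
    downstream survival, protein-correlation and drug-sensitivity screens. A
    built-in synthetic cohort generator with known ground truth makes every
    stage of the pipeline testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    survival,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
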