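Package: specmatch
Title: Metabolite Fingerprinting of 1D 1H-NMR Spectra by Reference
    Peak-List Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which known metabolites are present in a complex
    mixture from its one-dimensional 1H-NMR spectrum, by matching picked
    spectral peaks against curated reference libraries of single-metabolite
    peak lists.  Implements a significance score that favours peak-rich
    metabolites at equal match fraction, three search strategies (exact
    matching, chemical-shift-tolerant matching, and a greedy search that
    enforces mutual exclusion of peaks), spectral denoising and peak
    picking, seedable synthetic-library and noise generators, and
    evaluation machinery (confusion matrices, ROC/AUC, cut-off selection,
    recovery and ranking metrics) for benchmarking the search strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
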