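Package: csss
Title: Cell-Specific Signaling Signatures from Single-Cell Surprisal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes single-cell protein expression panels (multicolor
    flow cytometry or any cells-by-markers intensity table) into a reference
    (steady) state plus constraint-driven unbalanced processes using
    surprisal analysis, i.e. an SVD of the log-intensity matrix computed
    through the small markers-by-markers covariance matrix. Per-cell process
    amplitudes are thresholded on their sorted (sigmoid) distributions so
    that only tail cells count a process as active; each cell's set of
    active processes forms a cell-specific signaling signature (CSSS)
    barcode. Cells sharing a barcode form subpopulations, which are
    quantified per experimental condition and compared across conditions to
    flag expansions, contractions and emergent subpopulations (e.g. in
    response to radiotherapy). Includes per-process marker subnetwork
    export, a synthetic-data generator with planted processes and
    subpopulations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
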