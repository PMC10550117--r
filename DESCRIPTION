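Package: lucflow
Title: Single-Cell Luciferase Reporter Quantification by Flow Cytometry
Version: 0.1.0
Authors@R: person("LucFlow", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Quantifies Luciferase reporter expression in single cells from
    flow-cytometry list-mode data. Reads and writes FCS 3.0/3.1 files, applies
    the standard four-stage gating scheme (debris exclusion, singlet selection,
    dead-cell exclusion, CFSE spike-in deconvolution), and computes median
    fluorescence intensity, separation index, and spike-in-normalized fold
    change under two internal-control schemes (Luc-negative spike with
    cross-tube reference, or reporter-positive spike with cross-tube background
    estimation). Includes replicate precision (CV) reporting, comparison of
    flow-based fold changes with bulk luminescence assays, and a synthetic-data
    generator with ground truth that emulates the mixture structure of reporter
    tubes (debris, doublets, dead cells with reporter-independent
    autofluorescence, spiked controls) and per-tube staining effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
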