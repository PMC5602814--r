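Package: csccp
Title: Top-R Candidate Enumeration for Scaffold-Based Mass Spectrometry
    Structure Elucidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves the chemical substituent core combinatorial problem
    (CSCCP): given a molecular scaffold with per-position candidate
    sidechains, each carrying a mass and an attachment probability, and a
    molecular-weight window from an LC-MS peak, enumerate the R most
    probable substituted compounds whose total sidechain mass lies in the
    window. Implements the pseudo-polynomial top-R dynamic program over
    integerized masses with rolling cost buffers, bit-packed traceback
    compression into two 32-bit words per state, a device resource and
    feasibility model for the accelerator-imposed limits of the method, an
    exhaustive brute-force oracle, a deterministic synthetic scaffold and
    peak generator, and batch input/output over scaffold JSON and peak-list
    CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
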