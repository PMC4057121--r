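Package: refstab
Title: Reference-Gene Stability Analysis and Efficiency-Corrected qPCR
    Quantification for Avian Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating qPCR reference
    (housekeeping) genes and for efficiency-corrected relative
    quantification. Implements triplicate cycle-threshold (Ct) quality
    control with the 0.5-cycle deviation rule, amplification-efficiency
    estimation from ten-fold dilution series (E = 10^(-1/slope)), three
    independent gene-stability algorithms (geNorm M values with V(n/n+1)
    pairwise variation, a NormFinder-style inter/intra-group variance
    model, and BestKeeper descriptors with a mean-of-ranks consensus),
    and normalization of genes of interest to the geometric mean of
    selected reference genes with exact Mann-Whitney group testing.
    Ships a pan-avian candidate primer panel and per-species assay
    screen as fixtures, and a synthetic Ct-data generator emulating a
    songbird Area X singing experiment so the full pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
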