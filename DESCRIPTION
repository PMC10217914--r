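Package: mulliplex
Title: Species-Diagnostic Multiplex PCR and Melt-Curve Assay Design for
    DNA Barcodes
Version: 0.9.0
Authors@R:
    person("Mulliplex", "Developers", email = "mulliplex@example.org",
           role = c("aut", "cre"))
Description: Designs and validates in silico species-identification assays
    built on mitochondrial DNA barcodes (CO1, CYTB). Finds diagnostic SNPs
    that are fixed within one species and absent from all others, designs
    one-common-primer / N-species-specific-primer multiplex PCR panels whose
    amplicons are separated either by size on a gel ladder or by predicted
    product melting temperature, and validates panels with an IUPAC-aware
    in-silico PCR engine (3'-strict binding model), cross-reactivity
    matrices, primer-dimer screening, virtual gels, synthetic melt curves,
    concordance statistics and qPCR standard-curve fits. Ships the published
    four-species Mullidae (red mullet) panels as regression fixtures and a
    synthetic barcode generator with planted diagnostic sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
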