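Package: glycotriad
Title: Three-Level LC-MS N-Glycoprofiling of Granule Glycoproteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of complementary three-level LC-MS
    N-glycoprofiling experiments on neutrophil granule serine proteases:
    released reduced N-glycan alditols (negative mode), chymotryptic
    (glyco)peptides with CID/ETD fragmentation (positive mode), and intact
    multi-charge glycoprotein ESI spectra. Provides mass and isotopic
    distribution arithmetic, a constrained truncated-N-glycan structure
    space with exoglycosidase and PNGase F rules, a ground-truth-driven
    synthetic run generator, EIC-based relative quantitation, site
    occupancy estimation, charge-envelope deconvolution with proteoform
    matching, cross-level reconciliation, and glycosite structural context
    (large-probe solvent accessibility and active-site distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
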