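Package: magsort
Title: Order Retrieval for Magnetically Collected Serial Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recover the cutting order of ultrathin serial sections
    whose order was lost during magnetic collection onto silicon wafers.
    Simulates serial-section fiducial-bead and electron-microscopy texture
    imagery with known ground-truth order, detects fluorescent beads and
    measures their apparent diameters, computes pairwise section
    dissimilarities from matched bead constellations (summed absolute
    diameter differences) or from aligned tile image correlation (2 minus
    normalized cross-correlation), recovers the cutting order by solving an
    open traveling-salesman problem, and scores recovered orders against a
    ground truth with a per-link cost metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
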