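Package: pavecell
Title: Outline Morphometrics and Phylogenetic Signal for Leaf Pavement Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies leaf epidermal pavement-cell shape from traced
    outlines or binary segmentation masks: traditional shape descriptors
    (area, aspect ratio, circularity, solidity), elliptic Fourier analysis
    with first-harmonic normalization, principal component analysis of the
    descriptor table, species- and leaf-side-level aggregation, leaf-cell
    shape correlations, and tests for phylogenetic signal via global and
    local Moran's I with permutation nulls. Ships a synthetic-data
    generator producing lobed cell outlines with controlled solidity and
    aspect ratio, superellipse leaves, rasterized masks, clade-structured
    species datasets and matching phylogenies, so the whole pipeline is
    testable without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    mgcv,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
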