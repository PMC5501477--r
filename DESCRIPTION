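Package: fishtol
Title: Chronogram Grafting and Ranked-Classification Validation for the
    Fish Tree of Life
Version: 0.4.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assembling time-calibrated supertrees of bony fishes
    and validating ranked Linnean classifications against them. Donor crown
    subtrees are smoothed to ultrametricity with a deterministic mean-path
    smoother, rescaled to secondary crown-age calibrations, and grafted onto
    a calibrated backbone chronogram. Named taxa (megaclass to family) are
    tested for monophyly against the grafted tree, bootstrap support at each
    taxon's most recent common ancestor is extracted, and order-level and
    supraordinal taxa are endorsed under a strict greater-than-90-percent
    bootstrap rule with a corroboration escape hatch. The validated taxonomy
    is rendered as an indented ranked classification (phylogenetic order to
    the subordinal rank, families alphabetical) with summary counts, and
    rank-name endings are linted against nomenclatural suffix conventions.
    Seeded generators produce backbones, rate-noisy donor subtrees and
    taxonomies with planted non-monophyletic families so that every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
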