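Package: ffaudit
Title: Error Auditing for Machine-Learning Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies where and why a (machine-learning) force field fails
    on a molecular trajectory dataset. Reads extended-XYZ and NPZ-style
    trajectory bundles with reference energies and forces, aligns model
    predictions frame-by-frame, and computes force and energy error tables,
    per-element and per-atom error projections, kernel-density error
    distributions, smoothed error timelines, correlation scatter with robust
    outlier flags, two-stage configurational-space clustering (agglomerative
    on pairwise interatomic distances followed by k-means on energies) with
    per-cluster error profiles, radius-of-gyration and internal-coordinate
    series, and training-set representativeness checks. Includes a synthetic
    trajectory generator with planted error structure so every analysis stage
    is testable without external data, a batch audit driver that writes JSON,
    CSV and figure reports, and a command-line interface.
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
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
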