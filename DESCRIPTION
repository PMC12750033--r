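Package: cryofit
Title: Local Fit-to-Density Scoring and Local-Resolution Analysis for
    Cryo-EM Model Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing atomic models against cryo-EM density
    maps at the residue level. Implements segment-based Manders' overlap
    (SMOC) sliding-window fit-to-density scoring and its fragment-aligned
    difference score (delta-SMOC, including a 5-residue backbone/sidechain
    variant for high-resolution maps), windowed Fourier shell correlation
    local-resolution estimation from unfiltered half-maps with projection
    onto atoms, ensemble root-mean-square fluctuation analysis gated by
    model accuracy (lDDT, TM-score, interface similarity), and correlation
    of per-residue accuracy estimates with local resolution. A synthetic
    data module generates toy polymers, perturbed prediction ensembles and
    noisy half-map pairs with known ground truth so every analysis can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
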