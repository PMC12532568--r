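Package: lc3screen
Title: Whole-Organism High-Content Autophagy Screen Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image and trace analytics for whole-organism high-content
    autophagy screening. Implements larva localization and LC3-puncta
    segmentation for zebrafish image stacks (maximal projection, serial
    smoothing, background subtraction, body masking and puncta labeling),
    vehicle-normalized autophagic-flux readouts with and without lysosomal
    blockade (NH4Cl), dose-response profiles with toxicity masking, E_max
    hit ranking and four-parameter logistic IC50 fits, ratiometric
    mitophagy and membrane-potential indices (mito-QC, mtRosella,
    TMRM/MitoTracker, JC-10), Seahorse-style oxygen consumption rate
    summaries, and worm activity scoring. A seeded synthetic-data module
    generates every input modality with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
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
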