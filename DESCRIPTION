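Package: melachip
Title: Label-Free Quantitative Evaluation of Pigmented Epidermis-on-a-Chip Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading 3D pigmented epidermis-on-a-chip cultures from
    label-free brightfield images. Provides a vision-transformer
    encoder-decoder segmentation network (MEM-ViT) with a U-shaped
    multi-branch decoder trained with a composite Dice plus weighted
    cross-entropy loss, connected-component morphometry of melanin patches,
    optical density and transmittance quantification, a weighted composite
    quality score with good/poor classification, and a seeded synthetic
    brightfield image generator so the whole pipeline can be exercised
    without real data. Includes LabelMe polygon import, inter-annotator
    quality control, focus stacking, per-sample dataset splitting, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jpeg
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
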