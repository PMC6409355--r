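Package: peakcourse
Title: Temporal-Interaction Regression of Gene Expression on TF-Binding Peak Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how transcription-factor binding-peak characteristics in
    promoter regions (peak height, distance to the transcription start site, and
    peak width) predict gene expression across a developmental time course.
    Provides readers for bedGraph signal tracks, narrowPeak calls, BED6/GTF gene
    annotations and expression tables; strand-aware promoter windows and per-gene
    peak-feature extraction; a family of temporal-interaction linear models fitted
    by least squares with full regression inference (variance decomposition,
    F and t tests, adjusted R-squared) and bidirectional stepwise selection over a
    candidate set of time-modulated feature products; a threshold classifier for
    high versus low expression evaluated by seeded k-fold cross-validation against
    a small feedforward neural-network baseline; and a synthetic-data generator
    that emits matched tables, signal tracks and annotations from a known
    generative model so the whole pipeline is testable end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
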