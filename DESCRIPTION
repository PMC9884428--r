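Package: ihcscore
Title: Positive-Pixel Counting and H-Score Quantification for DAB
    Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies chromogenic immunohistochemistry (IHC) staining in
    RGB images of DAB/hematoxylin-stained tissue. Every region-of-interest
    pixel is classified as negative or weak/medium/strong positive using
    hue, saturation and intensity thresholds; per-bin positivity fractions
    and the weighted H-score (0-3 scale) are computed per sample, and
    groups of samples are compared with an unpaired two-sample t-test,
    standard errors and fold-change. A synthetic IHC image generator with
    planted per-class pixel fractions and cohort-level effect sizes
    provides ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
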