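Package: aggrequant
Title: Quantification of Aggrephagy Imaging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable quantification pipeline for fluorescence-based
    aggrephagy assays built around a tandem mCherry-GFP aggregation
    reporter: morphological top-hat segmentation of green/red puncta and
    their overlap ("white") area fraction, log-linear lysosomal
    degradation-rate estimation, puncta-count time courses and their area
    under the curve, FRAP trace normalization, single-molecule
    localization microscopy cluster analysis of autophagy receptors on
    aggregates (mean nearest-neighbour local density statistic with
    density-threshold clustering), and grey-value cross-section spread as
    an aggregate-compactness readout. Includes synthetic-data generators
    for every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    minpack.lm,
    pracma,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
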