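Package: siteform
Title: Site Form Estimation for Uneven-Aged Multispecies Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate and evaluate the site form (SF), a site
    productivity indicator for uneven-aged multispecies forests based on the
    height-diameter relationship of dominant trees rather than the
    height-age relationship used by the classical site index. Implements
    dominant-tree selection (100 tallest or 100 thickest trees per hectare),
    the Schumacher height-diameter model and its algebraic difference (ADA)
    and generalized algebraic difference (GADA) projection forms, three SF
    estimators at a reference diameter, relative-error profiling for
    reference-diameter selection, stand-level metrics (basal area, quadratic
    mean diameter, Reineke's stand density index, stand volume, periodic
    annual increment, importance value index), and correlation/regression
    evaluation of SF against productivity and density, stratified by species
    mixture. A synthetic-stand generator with known ground truth supports
    testing of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
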