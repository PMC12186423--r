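Package: seedscreen
Title: Automated Seed Counting and Transgene Segregation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts transgenic and wild-type seeds in stereomicroscope images
    and tests the counts against Mendelian segregation ratios to screen for
    single-locus T-DNA insertion lines. Supports fluorescent seed-coat markers
    (paired brightfield/fluorescence images) and colorimetric markers such as
    RUBY (single RGB image on a white background, classified in CIELAB space).
    Segmentation combines intensity thresholding, connected-component
    labelling, a median-area adaptive radial threshold, morphological
    cleaning, a chamfer distance transform and marker-seeded watershed
    splitting of touching seeds. Includes a ground-truth synthetic scene
    generator for validation, batch processing with CSV export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
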