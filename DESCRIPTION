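Package: tonguecolor
Title: Two-Stage Tongue Colour Diagnosis with k-Means Clustering Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies segmented tongue images into light red, red and deep
    red colour classes with a two-stage cascade: a support vector machine,
    trained on "clustering identifier" features selected from a k-means
    partition of the image in CIELAB space, first separates deep red tongues
    from the red/light-red group; an explicit CIELAB colour-range rule set
    with a luminance fallback then resolves red versus light red. Includes a
    synthetic tongue-image generator with ground-truth region masks, an
    evaluation harness (stratified cross-validation, confusion matrices,
    support-vector accounting, kernel comparisons) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
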