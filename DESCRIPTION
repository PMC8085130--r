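Package: ihcseg
Title: Seamless Segmentation and Classification of Nuclei in DAB&H-Stained
    Immunohistochemistry Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end detection, cluster splitting and
    immunopositive/immunonegative classification of cell nuclei in digital
    images of DAB&H-stained tissue sections. Implements integral-image
    (Bradley) adaptive thresholding on the HSV Value channel,
    mask-initialised region-based (Chan-Vese) boundary refinement,
    recursive distance-transform cluster splitting with a minimum-area
    filter, seam-free processing of large images by overlapped tiling with
    per-pixel majority-vote fusion, a 103-feature-per-channel shape/texture
    descriptor feeding a single-hidden-layer neural network classifier,
    object-wise precision/recall evaluation against point markers, and a
    synthetic DAB&H scene generator with exact ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
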