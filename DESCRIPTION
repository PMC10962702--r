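Package: hifishr
Title: High-Throughput DNA/RNA FISH Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for high-throughput combined DNA and
    nascent-RNA fluorescence in situ hybridization (DNA/RNA HiFISH) in
    multi-well plates. Provides cross-correlation registration of sequential
    acquisitions, nucleus segmentation with size and circularity quality
    control, Laplacian-of-Gaussian FISH spot detection, distance-transform
    normalized radial positioning, and allele-level Active / Inactive /
    No-Transcription classification, together with a synthetic plate
    simulator with ground truth for end-to-end validation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
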