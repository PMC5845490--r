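Package: wcebleed
Title: Bleeding Frame and Region Detection for Wireless Capsule Endoscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic detection of bleeding frames and bleeding regions in
    wireless capsule endoscopy (WCE) images. Frames are transformed to
    normalized RGB (chromaticity) space, a region of interest is extracted by
    two sequential linear chromaticity thresholds, fixed-bin histograms of a
    chromaticity plane restricted to the ROI serve as the feature vector for a
    K-nearest-neighbour classifier, detected bleeding regions are refined by
    morphological opening, and per-frame video labels are smoothed by removing
    isolated nonbleeding detections. Includes a seeded synthetic phantom
    generator with pixel ground truth so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    tiff,
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
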