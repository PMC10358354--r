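Package: bluefield
Title: Synthetic Field Image Generation from Blue-Screen Plant Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for turning indoor blue-screen plant photographs into
    labeled synthetic field images for object-detection training. Provides
    chroma-key plant segmentation with tight bounding boxes, scaled
    compositing onto soil backgrounds, mean-matching color correction in an
    8-bit CIELAB encoding, a pluggable image-translation interface with the
    contrastive unpaired translation (PatchNCE) loss mathematics, multi-plant
    scene assembly with automatic bounding-box labels (YOLO, Pascal VOC and
    CSV export), COCO/VOC-style detection metrics (interpolated-precision
    mAP), and a procedural fixture generator so the whole pipeline is
    testable without any external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    xml2,
    yaml,
    withr,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
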