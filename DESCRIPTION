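Package: lizardtherm
Title: Dual-Camera Thermography for Lizard Body-Part Temperature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-body-part surface temperatures of lizards (and other
    small ectotherms) from side-by-side RGB/thermal composite frames. The RGB
    panel is searched for a lizard and six body parts by a pluggable object
    detector; each bounding box is refined to a binary foreground mask and a
    single representative pixel; that pixel is mapped into the thermal panel
    with a four-point perspective transform; and the thermal pixel's colour is
    inverted to degrees Celsius through the image's embedded colour scale bar.
    Includes object-detection evaluation metrics (IoU, precision/recall,
    average precision, mAP), dataset split and augmentation bookkeeping,
    and a synthetic paired-scene generator with full ground truth so the whole
    pipeline is testable without real recordings or trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jpeg,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
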