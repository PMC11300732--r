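Package: mcpaste
Title: Overlap-Avoiding Copy-Paste Augmentation for Imbalanced Nuclei Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing class imbalance in annotated histopathology
    field-of-view datasets such as NuCLS. Implements an occupancy-map-guided,
    overlap-avoiding copy-paste augmentation for dense nuclei scenes, together
    with its surrounding pipeline: reading and writing 3-channel class/instance
    masks and COCO annotation documents, Reinhard color normalization of H&E
    images, count-based class weights for weighted cross-entropy and focal
    losses, detection and classification evaluation metrics (IoU matching,
    interpolated average precision, confusion matrices with a background label,
    balanced accuracy), and a synthetic nuclei scene generator for fully
    reproducible testing without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
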