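Package: histocbir
Title: Content-Based Image Retrieval for H&E Histopathology Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Query-by-example retrieval of Hematoxylin and Eosin stained
    tissue patches using deep features taken from intermediate layers of
    pre-trained convolutional backbones. Ships a versioned catalogue of nine
    backbone architectures with their extraction layers, input sizes and
    pixel normalizations; reduces three-dimensional activation maps to
    one-dimensional descriptors by global average pooling, global max
    pooling or flattening; stores descriptors with labels and provenance in
    an HDF5 feature bank; ranks candidates by cosine similarity; and
    evaluates retrieval with precision at k, per-class confusion matrices
    and gain/loss precision comparisons under a leave-one-out protocol,
    including the procedures that select the best reduction, layer and
    backbone. Deterministic synthetic generators make the full pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    jpeg,
    png,
    rhdf5,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
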