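Package: ora
Title: Object Reconstruction-Guided Attention for Robust Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A slot-based encoder-decoder classifier that iteratively
    reconstructs its current best object hypothesis and uses that
    reconstruction as top-down attention: a spatial mask over the input and
    a multiplicative binding bias between feature and object slots. An
    entropy-based stopping rule over the class-likelihood distribution
    yields a model "reaction time" in forward processing steps. Ships a
    deterministic synthetic glyph generator and a programmatic image
    corruption suite (noise, fog, stripe, zigzag, dotted line, spatter,
    blur, affine) so every algorithm is testable without downloads, plus
    readers for MNIST IDX and MNIST-C-style .npy containers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
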