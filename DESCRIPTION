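Package: spiraltrace
Title: Tremor Quantification from Hand-Drawn Archimedes Spirals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raster images of a patient's hand-drawn Archimedes
    spiral (scanned paper or tablet export) into a one-dimensional discrete
    signal of radial deviation versus arc length, and reduces that signal to
    a compact FFT parameter set with quantified truncation error, a
    tremor-frequency estimate in Hz, and an RMS tremor amplitude in pixels.
    The reference spiral is fitted from two user-supplied points, every ink
    pixel is mapped through a zone-family transform into a flattened space
    where spiral turns self-stitch into horizontal bands, and a single-valued
    profile is extracted, resampled and normalized. A synthetic-image
    generator renders tremulous drawings with known ground truth (rotation,
    stroke width, grey jitter, gaps, loops, crossings) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    tiff,
    signal,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
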