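Package: musclehisto
Title: Automated Quantification of Dystrophic Muscle Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Native implementations of four automated image-analysis pipelines
    for skeletal muscle cross-sections: counting membrane-damaged (Evans Blue
    Dye positive) fibers, counting and sizing regenerating (embryonic myosin
    heavy chain positive) fibers, measuring CD68 macrophage percent-area, and
    measuring Picrosirius-red collagen percent-area. Includes the underlying
    robust-background and minimum cross-entropy threshold selectors, a
    distance-transform watershed declumping segmenter, batch CSV export, and a
    synthetic muscle cross-section generator with exact ground truth for
    validating every pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
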