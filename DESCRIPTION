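Package: cryptocad
Title: Crypt-Architecture Texture Analysis and Neural Classification of
    Confocal Laser Endomicroscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided diagnosis pipeline for grey-scale confocal laser
    endomicroscopy (CLE) images of colorectal mucosa.  Extracts a
    seven-parameter description of crypt architecture per image (box-counting
    fractal dimension, gliding-box lacunarity, four grey-level co-occurrence
    matrix texture statistics, and a count of round glandular-crypt features
    obtained by marching-squares contour analysis with an area/perimeter
    roundness score), and classifies images as normal versus cancer with a
    two-layer feed-forward neural network trained with early stopping.
    Includes a synthetic phantom generator that emulates normal and
    adenocarcinoma crypt patterns with ground truth, and group-comparison
    statistics for the extracted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
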