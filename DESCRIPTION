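Package: cervroi
Title: Automatic Cervical-Vertebrae Region-of-Interest Extraction from
    Digital Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts the cervical-vertebrae region of interest from
    grayscale digital X-ray images. The pipeline complements the raw
    radiograph so dense anatomy is bright and the histogram is anchored at
    zero, binarizes it with a dynamic threshold taken at the first quartile
    of the intensity histogram, selects the largest connected component as
    the patient silhouette, locates the narrowest (neck) span by a row scan
    for the maximum background run in each half-image, crops a full-height
    strip between those columns, and enhances contrast by histogram
    equalization. Includes a seeded synthetic head-neck-shoulder phantom
    generator with ground-truth neck geometry, diagnostics (dynamic range,
    size-reduction percentage), broom-style tidiers, ggplot2 autoplot
    methods, and a small command-line interface. Reads single-frame
    grayscale DICOM (pixel data only), PNG, and TIFF at 8- or 16-bit depth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
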