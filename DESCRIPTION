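Package: ocuprost
Title: Automated Data-Driven Design of Custom Ocular Prostheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end digital design pipeline for custom ocular
    prostheses. Predicts a prosthesis shape for an anophthalmic socket by
    fitting a PCA statistical shape model to a partial socket depth map
    extracted from anterior-segment OCT raster volumes (column tracing with
    refraction, depth-bias and gaze corrections), and synthesizes a
    colour-matched appearance from a characterized photograph of the fellow
    eye: camera-to-CIELAB colour characterization, Daugman-style iris
    segmentation and texture unwrapping, seeded-watershed sclera
    segmentation, k-means palette extraction, Perlin staining and a
    procedural vein network. Outputs a print-ready textured OBJ model.
    Synthetic generators for prosthesis scans, OCT volumes and eye
    photographs support fully reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    farver
Config/testthat/edition: 3
RoxygenNote: 7.3.3
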