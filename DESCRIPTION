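Package: canalmorph
Title: Morphometry of Trans-Cortical Canals in Long-Bone Cortices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies trans-cortical canals in 3D micro-CT volumes of long-bone
    diaphyses. Segments cortical bone by thresholding, extracts intracortical void
    components and classifies them as vascular canals, osteocyte lacunae or the
    nutrient foramen, measures per-canal diameter (minor axis of the best-fitting
    ellipse of the canal-perpendicular cross-section) and polar orientation about
    the marrow-cavity axis, unwraps the endocortical surface into a cylindrical
    panoramic image, and compares groups with Mann-Whitney U and paired t tests.
    Includes a synthetic fibula phantom generator with a ground-truth ledger for
    end-to-end validation, and a 2D inter-edge distance operator for periosteal
    thickness measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
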