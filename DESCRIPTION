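Package: ctmotion
Title: CT-Based Micromotion Analysis of Implant Migration
Version: 0.1.0
Authors@R: person("ctmotion", "developers", role = c("aut", "cre"),
    email = "ctmotion@example.org")
Description: Measures rigid-body migration of an acetabular implant relative
    to the pelvic bone between two CT examinations, using either tantalum
    fiducial beads or the bone surface anatomy for the bone registration.
    Provides threshold segmentation of beads and metal structures, sub-voxel
    bead centroid extraction, matched-point (Kabsch) and iterative closest
    point rigid registration with radiostereometry-style quality metrics
    (condition number, mean error of rigid-body fitting), six
    degree-of-freedom decomposition of implant-versus-bone motion about the
    implant center of mass, ISO 16087 double-examination precision with a
    small-sample t coverage factor, and dose-length-product based effective
    dose estimation. A digital phantom generator produces paired CT volumes
    with known ground-truth migration so that the whole pipeline is testable
    without patient data. Reads and writes DICOM series, NIfTI-1 and
    MetaImage volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
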