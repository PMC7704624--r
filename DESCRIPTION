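Package: femcoord
Title: Automatic Femoral Landmarks, Axes, Planes and Bone Coordinate
    Systems from Surface Models
Version: 0.1.0
Authors@R:
    person("M.", "Keller", email = "mkeller@example.org",
           role = c("aut", "cre"))
Description: Fully automatic, alignment-robust detection of femoral
    landmarks, axes and planes on closed triangular surface models of a
    complete femur, and construction of three established femoral bone
    coordinate systems (Wu2002, Bergmann2016, TableTop).  The pipeline
    combines a single-atlas registration stage (principal-axes alignment,
    grid pre-registration, linear-blend-skinning template deformation and
    nonrigid iterative closest point) with a-priori-knowledge refinement
    stages (sphere fit of the head, ellipsoid fit of the shaft, iterative
    minimal-perimeter neck cuts, table-top-plane fixed point, unified
    sagittal plane of the condyles, epicondyle selection and
    intercondylar-notch detection).  A parametric synthetic femur
    generator with analytic ground truth provides the packaged atlas
    template and test subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
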