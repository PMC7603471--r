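Package: otoplan
Title: Curvature-Constrained Access-Canal Planning for Temporal Bone Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preoperative planning of nonlinear drilling trajectories through
    the temporal bone. Computes collision-free, curvature-bounded access
    canals from the skull surface to clinical targets (cochlea round window,
    internal auditory canal) with a bidirectional rapidly exploring random
    tree on cubic Bezier spiral splines, followed by sequential convex
    optimization of clearance to risk structures under curvature, safety
    distance and endpoint constraints. Includes exact signed-distance queries
    against triangle-mesh risk structures, label-volume preprocessing
    (largest connected component, volume-of-interest extraction, isosurface
    extraction), functional-evaluation metrics (success rate, mean minimal
    distance, failure rate, Dice, Hausdorff distance), and a seeded synthetic
    temporal-bone-like anatomy generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
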