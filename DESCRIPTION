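Package: CranioGuide
Title: Mirror-Based Planning, Registration and Drill Guidance for
    Craniofacial Recontouring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline computational core of an augmented-reality navigation
    workflow for recontouring of craniofacial fibrous dysplasia. Builds the
    planned post-operative surface by mirroring the healthy side of the skull
    across a least-squares midsagittal plane, performs paired-point (Kabsch)
    and iterative-closest-point rigid registration with fiducial error
    reporting, replays tracked drill-pose streams to produce distance-to-plan
    guidance with a 1 mm two-state colour logic, and evaluates surgical
    accuracy by paired points generated along surface normals in the surgical
    area. Includes a synthetic skull-phantom generator with full ground truth
    so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
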