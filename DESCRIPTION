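Package: shoalsight
Title: Collective Order, Visual Fields and Information Use in Shoal
    Foraging Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for multi-animal 2D trajectory data from
    group-foraging experiments. Computes individual- and group-level
    position and movement parameters (speed, distance and bearing to a
    stimulus, convex-hull membership and area, centroid statistics,
    polarization), reconstructs binocular and monocular visual fields by
    2D ray casting with neighbour-body occlusion, extracts first-response
    and arrival-latency events around stimulus presentations, and fits
    the associated statistical layer: all-subsets AICc candidate sets,
    Akaike weights, full model averaging with relative importance,
    Cook's-distance filtering, and behavioural repeatability from mixed
    model variance components. Includes an agent-based shoal simulator
    with a private/social detection hazard model so that the entire
    pipeline can be exercised and validated on synthetic data with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    lme4,
    mgcv,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
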