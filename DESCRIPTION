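Package: navopt
Title: Game-Theoretic Optimal Connectomes and Structure-Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Nash-equilibrium navigation-game (NNG) networks from node
    coordinates or arbitrary distance matrices, classifies structural
    connectome edges as optimal or nonoptimal against the game-theoretic
    model, predicts functional connectivity from structural connectivity via
    a rotated matrix-polynomial spectral map, scores predictions by
    upper-triangle correlation and by persistence of Betti-0 (connected
    component) differences across edge densities, fits distance-penalized
    generative control networks, and relates regional optimality to gene
    expression by partial least squares with a permutation null. Includes a
    synthetic-connectome generator with planted ground truth so the whole
    pipeline is testable end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
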