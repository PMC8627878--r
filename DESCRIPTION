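Package: oscontour
Title: Finding and Verifying Potentially Oscillating Feedback Contours in
    Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects potentially oscillating contours in typed bipartite
    gene/metabolic network graphs (substance and reaction nodes with
    substrate, product and signed regulator edges): directed mass-flow
    paths closed by a single terminal inhibitory regulator edge. For each
    contour it reconstructs a Goodwin-type ordinary differential equation
    model (Hill-inhibited entry reaction, linear mass-action chain,
    first-order degradation), integrates it with stiff-capable solvers,
    classifies trajectories as steady, damped, sustained, growing or
    irregular, and scans the Hill-exponent/half-saturation plane for
    oscillatory regimes. Ships a registry of classical biochemical
    oscillator models used to calibrate the classifier, a synthetic graph
    generator with planted contours, and the tryptophan-biosynthesis
    feedback loop as a built-in worked example. Reads and writes SBML,
    GraphML and a plain tab-separated edge-table dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
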