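Package: crnconnect
Title: Path Connectivity of Multistationarity Regions of Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Certifies path connectivity of the parameter region of
    multistationarity of a mass-action chemical reaction network. Computes the
    critical polynomial of the convex (flux-cone) parametrization of the
    positive steady-state set as an exact symbolic determinant, and decides
    existence of a strict separating hyperplane of its signed support by exact
    rational linear programming. Includes structural preconditions
    (conservativity, exclusion of relevant boundary steady states via minimal
    siphons), exact extreme-ray computation for flux cones, the
    reverse-reaction network reduction that lifts connectivity conclusions to
    the original network, and programmatic builders for a corpus of cell
    signaling motifs (phosphorylation cycles, signaling cascades, reciprocal
    enzyme regulation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
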