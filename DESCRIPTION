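Package: triocms
Title: Evolution of Trioecy via Cytoplasmic Male Sterility in Androdioecious Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic genotype-frequency recursions for the invasion and
    maintenance of cytoplasmic male sterility (CMS) in hermaphroditic and
    androdioecious plant populations with XY sex determination and a
    Y-linked (partial) fertility restorer. Implements three variants of the
    mating system (no pollen limitation; pollen limitation with ovule
    abortion; pollen limitation with delayed selfing), closed-form invasion
    and fixation thresholds, numerical Jacobian stability analysis at
    boundary equilibria, forward simulation to equilibrium with
    invasion-order scenarios, bisection threshold finding, and phase-diagram
    classification of the resulting sexual systems (hermaphroditism,
    androdioecy, gynodioecy, trioecy, dioecy, extinction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
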