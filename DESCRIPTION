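Package: netmoa
Title: Mechanism-of-Action Ensembles on Signed Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Samples ensembles of candidate drug mechanisms of action (MoAs) over a
    directed signed protein-interaction network. Drug-target stimuli are clamped at
    +/-1 and propagated through hyperbolic-tangent node responses with tunable edge
    weights; weights are fitted against active/inactive node restrictions by
    simulated annealing, and many independent fits form an ensemble of plausible
    mechanisms ("prototype patients"). The ensemble is stratified into quartile
    groups by the mean signal reaching phenotype effectors (TSignal), groups are
    compared geometrically (modified Hausdorff distance, dispersion, UPGMA
    dendrogram, classical multidimensional scaling), differential biomarker
    proteins are extracted by best-classifier search with Mann-Whitney testing and
    opposite-sign filtering, and a random-walk-with-restart proximity scorer
    provides a network-based cross-check. Includes a synthetic-instance generator
    with planted ground truth so the whole pipeline is testable without
    proprietary network or effector data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
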