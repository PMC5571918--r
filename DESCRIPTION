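Package: phyquart
Title: Quartet Tree Evaluation with Polarized Site-Patterns and Likelihood-Based Convergence Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the three possible topologies of a four-taxon
    nucleotide alignment by combining a Hennigian classification of
    split-supporting site-patterns (apomorphic versus plesiomorphic under
    both polarities of the internal branch) with maximum-likelihood
    estimates of the convergent support expected under the competing
    topologies.  Provides the GTR+Gamma+I likelihood machinery on quartet
    trees, a sequence simulator for the classic long-branch-attraction
    branch-length designs, a maximum-likelihood topology-selection
    baseline, and a simulation-grid runner for reconstruction-success
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Collate: 
    'patterns.R'
    'alignment.R'
    'experiments.R'
    'substmodel.R'
    'fit.R'
    'mltree.R'
    'phyquart-package.R'
    'score.R'
    'simulate.R'
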