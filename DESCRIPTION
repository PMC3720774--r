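Package: baconet
Title: Bayesian Clustering Over Networks for Time-Course Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from short time-course
    expression data with a dynamic Bayesian network whose genes are
    probabilistically clustered by an integrated Gaussian mixture model.
    The model is fitted by coordinate-ascent variational Bayes with
    automatic-relevance-determination priors on the cluster-level
    transition matrix; the number of clusters is selected by maximising
    the variational marginal-likelihood bound over restarts and cluster
    counts. Includes readers and writers for DREAM4-style time-series
    tables and gold-standard edge lists, signed edge ranking from the
    fitted transition matrix, AUROC/AUPR evaluation of ranked edges, a
    generative simulator for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'formats-io.R'
    'linear-model.R'
    'vb-engine.R'
    'fit.R'
    'model-selection.R'
    'edge-ranking.R'
    'evaluation.R'
    'simulate.R'
    'cli.R'
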