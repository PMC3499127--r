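Package: swarmfit
Title: Simulation and Likelihood-Based Model Selection for Collective
    Animal Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulators and a likelihood-based inference engine
    for collective animal behaviour. Implements ring-arena direction
    switching with Markovian and memory-carrying interaction rules, the
    alignment-in-radius self-propelled particle model and its order
    parameter phase transition, Weber's-law pheromone trail following with
    deposition and evaporation, and double-bridge choice dynamics. A model
    selection engine provides sequence likelihoods, maximum likelihood
    fitting, information criteria, Laplace-approximate marginal likelihoods
    and Bayes factors, least-squares force matching for planar interaction
    models, and a route-mixture predictor for paired journeys from repeated
    solo paths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    igraph,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'trajdata.R'
    'models.R'
    'ring-sim.R'
    'vicsek.R'
    'ant-trail.R'
    'inference.R'
    'force-matching.R'
    'route-mixture.R'
    'cli.R'
    'zzz.R'
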