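Package: trswitch
Title: Inferring Transcriptional Regulation Logic from Dynamic Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers which subset of candidate transcription factors regulates a
    target gene, and the logic of that regulation, from time-series mRNA
    expression observed across multiple experimental conditions. The target is
    modelled by a linear ordinary differential equation whose transcription
    rate is piecewise constant, switching whenever a regulator profile crosses
    an activation threshold; each observed joint activation state owns a single
    transcription rate shared across experiments. Posterior inference on the
    regulator set, activation thresholds, degradation rate and noise model is
    carried out by a reversible-jump Markov chain Monte Carlo sampler with
    birth, death, swap and threshold moves and a plug-in weighted least squares
    likelihood. Includes spline-based regulator-proxy preprocessing with wild
    bootstrap diagnostics, seeded synthetic-data generators for benchmark
    regulatory networks, and posterior summaries that rank regulator sets and
    classify each regulator as activator, repressor or conditional.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
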