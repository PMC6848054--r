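Package: aimdp
Title: Active Inference for Discrete Markov Decision Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-state active inference agents for partially observed
    Markov decision processes. Builds categorical generative models
    (likelihood, transition, preference, prior arrays and a policy set),
    performs variational belief updating by mean-field fixed-point
    iteration under two objective functions -- the variational free energy
    with an expected-free-energy policy prior, and a generalised free
    energy in which future outcomes are treated as latent variables -- and
    runs closed-loop trials against a simulated environment. Includes the
    classic T-maze epistemic-foraging task, a brute-force enumeration
    oracle for exact evidence on small models, and a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
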