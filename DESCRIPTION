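Package: stripemorph
Title: Comparative Phylogenetics of White-Stripe Pattern Evolution in
    Clownfishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of simple ornamental color
    patterns on a time-calibrated phylogeny, motivated by the zero-to-three
    vertical white stripes of clownfishes (Amphiprionini).  Implements
    continuous-time Markov (Mk) models of discrete characters with arbitrary
    constrained transition-rate matrices, maximum-likelihood fitting,
    likelihood-ratio tests and AICc model tables, marginal ancestral-state
    reconstruction, stochastic character mapping with endpoint-conditioned
    path sampling by uniformization, state-dependent diversification (MuSSE)
    likelihoods with shared speciation and extinction rates and a sampling
    fraction, phylogenetic generalized least squares under Brownian motion,
    dorsal-fin lobe and body-elongation indexes, and a polymorphism-aware
    identical-pairs randomization test of the species-recognition hypothesis
    for sympatric communities.  Seeded generators for birth-death trees,
    Markov characters, Brownian traits and community pools make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    Matrix,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
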