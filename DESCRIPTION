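Package: probreserve
Title: Chance-Constrained Reserve Selection by Simulated Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Minimum-set spatial conservation prioritization where every
    conservation feature must meet its representation target with a
    user-specified probability. Planning units carry per-site loss
    probabilities (threat mode) or per-feature existence probabilities
    (species mode); the probability that a selected reserve system captures
    at least the target amount of a feature is computed exactly via the
    Poisson-binomial distribution or approximated by a normal upper-tail
    bound. Solutions minimise a four-term objective (site cost, boundary
    length, representation shortfall penalty, probability shortfall penalty)
    by simulated annealing with iterative improvement, with an exhaustive
    optimum available for small instances. Reads and writes the Marxan-style
    plain-text table dialect, including the probability extensions, and
    provides a command-line entry point, report writers, and seeded random
    landscape generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
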