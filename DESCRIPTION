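Package: pfspeller
Title: Particle-Filter Decoding and Simulation for P300 Speller Flashing Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of a P300 brain-computer-interface speller.
    Builds flash codebooks for the row-column, checkerboard and combinatorial
    stimulus paradigms on a 6x6 character grid, a word-prefix probabilistic
    automaton language model with frequency-derived transition probabilities,
    and a sequential Monte Carlo (particle filter) decoder with dynamic
    stopping, retroactive error correction and predictive spelling. Includes a
    two-Gaussian generative model of per-flash classifier scores, an ERP-like
    epoch generator with stepwise linear discriminant analysis (SWLDA)
    calibration, and the standard typing metrics (Wolpaw bit rate, information
    transfer rate, Levenshtein-distance accuracy, selection rate under an
    SOA-based timing model), with table-style aggregation and nonparametric
    comparison across paradigms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
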