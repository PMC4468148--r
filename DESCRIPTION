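Package: voidesign
Title: Value-of-Information Sample-Size Estimation for Non-Inferiority Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare frequentist and decision-theoretic sample-size
    estimation for non-inferiority trials. Implements the Blackwelder
    one-sided non-inferiority test and sample-size formula, a probabilistic
    four-state Markov cohort model of elastic compression stocking therapy
    for the prevention of post-thrombotic syndrome after deep vein
    thrombosis, probabilistic sensitivity analysis on the net monetary
    benefit scale, Bayesian updating of trial evidence (conjugate
    beta-binomial incidence updates and a normal update of the log relative
    risk), and nested Monte Carlo value-of-information analyses (EVPI,
    EVPPI, EVSI and the expected net benefit of sampling) that yield an
    optimal trial size.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
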