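Package: afentropy
Title: Real-Time Atrial Fibrillation Detection from RR Intervals via
    Symbolic Dynamics and Coarse Shannon Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Beat-by-beat screening of atrial fibrillation (AF) in heart-rate
    (RR-interval) streams. Instantaneous heart rates are coarse-grained into a
    64-state symbol alphabet, consecutive symbol triples are packed into integer
    words, and a normalized ("coarse") Shannon entropy of the word distribution
    over a sliding 127-word window is compared with a decision threshold. The
    entropy is maintained recursively with integer lookup-table arithmetic so
    each beat costs a constant number of integer operations, one multiply and
    one divide. Includes a floating-point entropy oracle, beat-level confusion
    metrics and ROC threshold sweeps, readers and writers for beat CSV and
    rdann-style rhythm-annotation text, and a seeded synthetic generator for
    sinus-rhythm, AF and paroxysmal beat streams with ground-truth labels.
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
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
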