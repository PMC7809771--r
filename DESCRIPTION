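Package: spinmrf
Title: Nuclear Compartmentalization States from TSA-seq, DamID and Hi-C via a
    Hidden Markov Random Field
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns genome-wide nuclear compartmentalization ("SPIN") states
    to fixed-size genomic bins by integrating multiple one-dimensional
    proximity signals (TSA-seq, DamID) with a graph of significant Hi-C
    interactions under a hidden Markov random field. Includes the signal
    processing front end (log2 enrichment scores, Hanning smoothing,
    re-binning, Repli-seq fraction percentages), observed/expected Hi-C
    significance calling with per-chromosome Weibull tails, Gaussian-mixture
    initialization, loopy belief propagation inference, mean-field EM
    parameter estimation, model selection over the number of states, a
    planted-truth synthetic-data generator, and downstream evaluation
    (fold-enrichment stratification, boundary transition profiles, and
    random-forest prediction of multi-fraction replication timing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    mclust,
    fitdistrplus,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
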