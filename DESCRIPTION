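Package: rxseq
Title: Clustering Biologic DMARD Prescription Sequences with Mixture Markov Models
Version: 0.1.0
Authors@R:
    person("rxseq", "maintainers", email = "rxseq@example.org", role = c("aut", "cre"))
Description: Builds per-patient biologic/targeted-synthetic DMARD class sequences
    from EHR-style prescription records using 3-month encounter windows, clusters
    the sequences with a maximum-likelihood mixture of first-order Markov chains
    fitted by EM, selects the number of clusters by AIC and the Calinski-Harabasz
    index, and profiles clusters against CDAI disease-activity trajectories.
    Includes a synthetic-cohort generator so the whole pipeline is testable
    without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
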