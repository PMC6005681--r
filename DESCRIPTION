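Package: amdetect
Title: Amplitude-Modulation Detection: Psychometrics, Cortical Neurometrics,
    and Brainstem Envelope-Following Responses
Version: 0.1.0
Authors@R:
    person("AM", "Detect Maintainers", email = "amdetect@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Go-Nogo amplitude-modulation (AM) detection
    experiments with simultaneous auditory-cortex recordings, as used to study
    developmental conductive hearing loss. Provides psychometric fitting
    (cumulative-Gaussian, d-prime, temporal modulation transfer functions),
    single-unit neurometrics (best-window firing-rate d-prime, monotonicity
    index, vector strength with Rayleigh test, choice probability),
    spike-train pattern classifiers (firing rate, van Rossum, K-means, Rcorr),
    linear population decoding of 1-ms binned spike counts with a built-in
    maximum-margin classifier, envelope-following-response and auditory
    brainstem response threshold analysis, hierarchical bootstrap group
    statistics, and a seeded synthetic-data generator that emulates behavioral
    sessions, cortical spike trains, and brainstem waveforms so every stage is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
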