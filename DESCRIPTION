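Package: neomat
Title: Quantitative EEG Maturation Analysis for Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts maturational features from 2-channel bipolar EEG of
    extremely preterm infants (relative band powers, spectral edge
    frequencies, burst continuity via nonlinear-energy-operator detection of
    spontaneous activity transients, and multiscale-entropy complexity) and
    relates them to postmenstrual age with linear mixed-effects brain-age
    models and to MRI-derived structural metrics with partial correlation and
    multiple regression.  Includes a two-tier synthetic cohort generator
    (feature-space mixed-model cohorts and trace-discontinu EEG waveforms
    with ground-truth burst annotations) so the whole pipeline can be
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
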