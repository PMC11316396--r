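Package: carollia
Title: Bat-Piper Interaction Analysis from Ultrasonic, Camera-Trap, Diet and
    Fruit-Scent Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the mutualism between short-tailed fruit
    bats (Carollia) and Piper plants across forest and gap habitats. Implements
    a two-pass semi-automated ultrasonic screening algorithm (Butterworth
    band-pass filtering plus Welch peak-frequency decision), spectrogram-based
    echolocation call measurement and call-type classification, camera-trap
    visit-event tabulation and temporal activity profiles, fruit-scent volatile
    (VOC) dataset construction, and the accompanying statistical battery:
    Monte-Carlo chi-square tests on contingency tables, logit-transformed diet
    ANOVAs, Wilcoxon rank-sum tests with Benjamini-Hochberg correction, a
    nonparametric multivariate ANOVA-type test with relative treatment effects,
    and Blomberg's K for phylogenetic signal. A synthetic-data module generates
    ultrasonic scenes, event logs, diet tables, VOC matrices and phylogenies
    with known ground truth so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
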