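Package: larvatox
Title: Quantitative Phenotyping of Zebrafish Larvae in Toxicant-Rescue Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for quantitative phenotyping of
    zebrafish larvae in drug toxicity and rescue experiments. Implements
    video cardiography (heart rate from dynamic pixel intensity, kymographs,
    chamber contraction from systolic/diastolic perimeters), locomotion
    scoring (spontaneous displacement binning and touch-evoked response
    classification), polarized-light birefringence quantification of trunk
    muscle, LC50 estimation by empirical-logit regression, qPCR
    standard-curve quantification with reference-gene normalization, and the
    group-comparison statistics layer (Welch ANOVA with Games-Howell
    post-hoc, Kruskal-Wallis with pairwise Mann-Whitney, Student's t-test).
    A synthetic-data generator with analytic ground truth stands in for raw
    recordings so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    withr,
    ggplot2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
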