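Package: gvhdscore
Title: Multi-Observer Histological Scoring and Grading of Colonic Acute
    Graft-versus-Host Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reproducible histopathological assessment of acute
    graft-versus-host disease (GvHD) in colon biopsies scored by several
    observers. Implements the per-rater morphology data model (crypt
    apoptotic body counts plus six ordinal parameters), four
    morphology-only grading systems (adapted Lerner, Sale, Melson and NIH
    categories), additive severity sum scores built from panel means,
    inter-rater agreement statistics (75 percent consensus rule, Fleiss
    kappa, two-way agreement single-measure intraclass correlation,
    pairwise Spearman correlation), association of histology with ordinal
    clinical outcomes (Kruskal-Wallis and Mann-Whitney comparisons,
    chi-square cross-tabulation with adjusted standardized residuals, CAB
    count cut-off sweeps), and a seeded synthetic cohort generator in
    which a latent severity drives both multi-rater morphology and
    clinical outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
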