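Package: wssvar
Title: Variability Analysis of Aneurysm Wall Shear Stress Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing and variability analysis for multi-team
    computational-hemodynamics studies of intracranial aneurysms, modelled
    on the centralized analysis of the 2015 International Aneurysm CFD
    Challenge. Reads triangulated lumen surfaces carrying wall shear stress
    (WSS) fields and planar cross-sections carrying velocity data, isolates
    the aneurysm sac and a parent-artery band with exact plane clipping,
    and computes standardized parent-artery (diameter, flow rate, Reynolds
    number, Poiseuille and calculated WSS, outflow division) and sac
    (AWSS, MWSS, LSA and their parent-normalized variants) hemodynamic
    parameters. A cohort-statistics layer provides quartile coefficients
    of dispersion, case-average summaries with missing-data rules,
    D'Agostino-Pearson and Kruskal-Wallis/Dunn tests, rank-order consensus,
    and intra-team percent differences. A synthetic-cohort generator with
    closed-form ground truth emulates a multi-team challenge so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
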