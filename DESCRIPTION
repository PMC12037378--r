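Package: glycorr
Title: Correcting HbA1c for Shortened Red Blood Cell Lifespan in Type 2 Diabetes
Version: 0.1.0
Authors@R: person("glycorr", "maintainers", email = "maintainers@glycorr.dev",
    role = c("aut", "cre"))
Description: Tools for quantifying and rectifying the effect of shortened red
    blood cell (RBC) lifespan on HbA1c measurements in type 2 diabetes.
    Implements the hemoglobin glycation index (HGI) and the ADAG average
    glucose conversion, RBC lifespan estimation from CO breath measurements,
    lifespan-group classification with piecewise linear HbA1c correction,
    breakpoint (inflection) detection on the HGI-lifespan relation,
    subgroup correction-model fitting with rank-based group statistics and
    odds ratios, ROC/AUC and calibration validation, a seeded synthetic
    cohort generator, and an end-to-end pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
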