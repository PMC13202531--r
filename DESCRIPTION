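Package: ivtpk
Title: Intravitreal Two-Compartment Pharmacokinetics from Ocular Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intravitreal clearance of radiolabelled antibodies
    measured by longitudinal PET imaging. Implements the open two-compartment
    model of ocular drug disposition (biexponential decline of eye activity,
    hybrid and micro rate-constant parameterisations), weighted nonlinear
    least-squares fitting of per-eye time-activity curves with a
    goodness-of-fit battery (R2, standard error of estimate, RMSE, AICc,
    parameter CV%), derived pharmacokinetic quantities (phase half-lives,
    AUC to infinity, mean residence time), PET-side quantification (decay
    correction, first-frame normalisation, ellipsoidal region-of-interest
    extraction from voxel volumes, percent injected dose per organ,
    theoretical-blood-volume activity), semiquantitative anterior/posterior
    autoradiograph splits, cohort simulation with known ground truth, and
    group-level summaries and comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    readr,
    minpack.lm,
    deSolve,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
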