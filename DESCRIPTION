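Package: strainpost
Title: Post-Processing of Speckle-Tracking Cardiac Deformation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-processing of time-sampled myocardial
    deformation (strain and strain-rate) curves exported as plain text by
    speckle-tracking echocardiography software. Segments one cardiac cycle
    into its six mechanical phases from valve events and ECG landmarks,
    detects per-segment peak systolic strain under two selection rules
    (window minimum, and the 75 percent positive-peak rule used by
    commercial packages), computes Global Longitudinal Strain (GLS) over
    the AHA 18-segment left-ventricular model, derives strain rate from
    strain, and runs a normality-gated method-agreement battery
    (Shapiro-Wilk, Q-Q, Pearson/Spearman, paired t / Wilcoxon,
    Bland-Altman with equivalence criteria). Includes a generator of
    phase-structured synthetic strain, strain-rate and ECG signals with
    known ground truth, a packaged 48-subject paired-GLS validation
    series, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
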