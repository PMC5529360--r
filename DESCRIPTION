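Package: resiflex
Title: Residue Stability from MD Trajectories and Clinical Correlates of
    Acquired EGFR T790M Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of protein-inhibitor molecular dynamics
    trajectories into per-residue stability statistics: least-squares
    (Kabsch) best-fit superposition of every frame onto a reference
    structure, construction of the trajectory-average structure, per-residue
    mean and standard deviation of the atom-averaged displacement from that
    average structure, reordering of residues by their mean distance to a
    focal residue (EGFR T790 by default), and cumulative average stability
    curves for comparing mutant-inhibitor complexes. Also provides the
    matched clinical cohort analysis: contingency tables and proportions for
    acquired-T790M outcomes, two-sided Fisher's exact tests, and categorical
    attribute ranking (chi-squared, information gain, symmetrical
    uncertainty, correlation, ReliefF). Synthetic trajectory and cohort
    generators with known ground truth support validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
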