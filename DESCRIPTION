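Package: opikin
Title: Objective Performance Indicators from Robotic Surgical Console Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes step-level objective performance indicators (OPIs) from
    timestamped robotic-console kinematic streams and activity events recorded
    during robotic Roux-en-Y gastric bypass: task duration, active console
    time, per-hand active-time percentages, instrument path length and speed,
    bimanual dexterity, and convex-hull workspace volume with time- and
    path-length normalizations. Maps raw step annotations onto an eight-step
    procedure ontology, compares surgeon cohorts with a normality-gated
    two-sample procedure (Student t or Mann-Whitney U), and ships a seeded
    synthetic case-bundle generator with controllable per-step effects for
    ground-truth validation and statistical calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
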