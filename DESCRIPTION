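Package: facialdti
Title: Diffusion Tensor Analysis of the Intratemporal Facial Nerve with
    Synthetic Phantom Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end diffusion tensor imaging (DTI) group analysis of
    thin curved nerve tracts, built around the intratemporal facial nerve.
    Simulates bilateral nerve phantom cohorts with known ground truth
    (monoexponential tensor signal, Rician noise), fits the diffusion
    tensor by log-linear least squares, derives FA/MD/AD/RD scalar maps,
    runs deterministic FACT streamline tractography with FA, angle and
    length thresholds, fuses per-subject tract maps into a maximum
    probability map (MPM) by strict majority voting across subjects,
    extracts MPM-based scalar indexes per subject and side, and performs
    the paired and pooled-variance unpaired two-tailed t-tests and
    Kolmogorov-Smirnov normality checks of a left/right and
    affected/healthy-side group comparison. Reads and writes NIfTI-1
    volumes, FSL-style bval/bvec gradient tables, TrackVis .trk
    streamline files and CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
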