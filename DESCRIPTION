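Package: hicpentad
Title: Average Chromatin Compartment (Pentad) Analysis of Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Pentad", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Distance-dependent pile-up analysis of Hi-C interactions within
    and between A/B chromatin compartments. Reads binned contact matrices in
    the cooler (HDF5) standard together with a compartment signal (typically
    PC1) in bedGraph format, converts contacts to observed-over-expected,
    extracts compartment-by-compartment areas, rescales them with bilinear
    interpolation and median-averages them into the five-panel "pentad"
    (average compartment) in cis, trans, or stratified by genomic distance.
    Quantifies per-chromosome compartment strength as the ratio of mean
    within-compartment to mean (edge-cropped) between-compartment
    observed-over-expected contacts, and compares conditions with the
    Wilcoxon signed-rank test. Includes a seeded synthetic Hi-C generator
    with planted compartment structure for calibration and testing, and a
    multi-command CLI entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with numpy and h5py on the PATH
    (used for reading/writing cooler HDF5 containers)
Config/testthat/edition: 3
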