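Package: digitclock
Title: Digit Clock and Phalanx-Claw Transition Analysis for Amniote Limb
    Development
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of digit development in
    amniote limbs under a "digit clock" model: per-digit joint-formation
    schedules within a fixed developmental window, extraction of purple
    in-situ stain intensity profiles along digit polylines from
    whole-mount RGB images, length-normalized phase correlation of
    cyclical Gdf5-like expression between digits, scoring of joint
    domains and phalanx elements, calling of the phalanx-claw transition
    from marker on/off tables, and a minimal per-digit differential
    abundance screen over TPM matrices with Benjamini-Hochberg
    correction.  Ships a curated amniote digit phenotype table and a
    fully ground-truthed synthetic-data generator so that every analysis
    stage is testable without external downloads.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
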