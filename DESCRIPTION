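Package: iphplc
Title: Protein Expression Profiling from Immunoprecipitation HPLC Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies relative protein expression from immunoprecipitation
    high-performance liquid chromatography (IP-HPLC) UV chromatograms.
    Implements baseline-corrected trapezoidal peak integration (mAU*s),
    negative-control subtraction, square-root area normalization, percent
    expression versus control with proportional housekeeping-baseline
    rescaling, replicate statistics (population SD, SEM, quality-control
    flags), change-band classification, antibody-panel bookkeeping with
    overlap (cross-listed) references, an in situ cell proliferation index,
    figure-ready data reductions (line, star, and dot plots), and a fully
    seeded synthetic-chromatogram generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
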