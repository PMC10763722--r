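Package: TitinScope
Title: Sarcomeric Titin Epitope Nanostructure and Truncating-Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of truncated-titin integration into the
    cardiac sarcomere. Provides a residue-coordinate model of the titin IC
    isoform with band-region classification and truncated-protein mass
    prediction, cohort-level truncating-variant summaries, a generative
    kinematic model of anti-titin epitope positions in stretched sarcomeres,
    a seeded simulator of STED-like two-channel line profiles and SDS-agarose
    gel lanes, a Gaussian epitope profiler (peak detection, multi-Gaussian
    fitting, sarcomere assignment, intensity-fluctuation quality control),
    gel densitometry with molecular-weight calibration and titin
    stoichiometry ratios, and normality-gated statistics with
    sarcomere-length regressions and slope-equality tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
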