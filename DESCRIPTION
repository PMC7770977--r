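Package: polarhythm
Title: Nonparametric Detection and Characterization of Daily and Ultradian
    Transcriptome Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rank-based detection of rhythmic transcripts in short expression
    time series sampled over a single day, using Jonckheere-Terpstra statistics
    along cyclic umbrella orderings at candidate periods (24, 20, 16, 12 h),
    with exact permutation nulls on small designs and tie-corrected normal
    approximations otherwise, joint Benjamini-Hochberg adjustment, and
    daily/ultradian classification. Includes deterministic models of the solar
    elevation and tidal height cycles transcript phases are compared against,
    phase and amplitude estimation on folded profiles, cross-station
    rhythm-architecture comparison, hypergeometric over-representation
    analysis, and a synthetic-data generator with planted rhythms for power
    and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
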