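Package: fossilsieve
Title: Screening Fossil Calibrations by Per-Fossil Penalized-Likelihood Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for vetting fossil calibration candidates before Bayesian
    divergence-time estimation. Each candidate fossil is used alone to convert
    a maximum-likelihood phylogram into a chronogram under penalized-likelihood
    rate smoothing; fossils whose single-fossil chronograms yield ages outside
    the interquartile region at monitored reference nodes are culled, fossils
    at weakly supported nodes (three or fewer surviving records) are removed,
    and the oldest surviving minimum age per node becomes that node's
    calibration. A minimal Bayesian node-dating stage under an
    independent-rates relaxed clock consumes the selected calibrations, and a
    chrono-biogeographic summary bins fossil occurrences by family, region and
    geologic time. A synthetic-data generator (birth-death chronograms,
    Poisson-noised branch lengths, fossil registries with planted misleading
    records) makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
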