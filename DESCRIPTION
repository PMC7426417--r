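Package: synieg
Title: Simulation and Quantification of Synthetic Immediate-Early Gene Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multi-step signal decoding by synthetic
    immediate-early genes (SynIEGs). Provides a deterministic (optionally
    stochastic) kinetic simulator of Erk-driven gene circuits with
    transcript- and protein-level regulation (Zfp36-like adaptation,
    microRNA gating of translation, Erk-stabilized degrons), a renderer
    that turns simulated trajectories into realistic multi-channel
    z-stack time-lapse movies, and the quantification chain used for
    live-cell transcription-site imaging: z max-projection, 2D Gaussian
    fitting of transcriptional foci, nuclear reporter traces,
    baseline-anchored AUC and fold-change statistics, and duration-filter
    and AND-gate characterization with two-sample t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
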