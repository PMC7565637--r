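Package: pentafiber
Title: Pentameric Beta-Bracelet Viral Fiber Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence and structure analysis of pentameric viral head
    fibers built from beta-bracelet repeats, the period-8 structural
    motif found in the delta fiber proteins of Orsay-like nematode
    viruses. Provides a deterministic consensus scanner for strict and
    relaxed beta-bracelet repeats with heptad coiled-coil register
    assignment and domain segmentation, an additive fiber-architecture
    length model, quantitative geometry of five-fold symmetric fiber
    coordinates (axis fitting, rise per repeat, strand tilt, radial and
    channel profiles, main-chain hydrogen-bond census), calculators for
    assembly biochemistry (oligomeric state from intact mass, fiber
    stoichiometry from gel densitometry, electron-microscopy particle
    statistics), and seeded synthetic-data generators so every analysis
    stage can be exercised against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
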