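Package: MPSkeleton
Title: Quantitative Analysis of the Neuronal Membrane-Associated Periodic Skeleton
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the ~190-nm membrane-associated periodic
    skeleton (MPS) of neurons from single-molecule localization microscopy
    data: 1D projection of localizations onto axon segment axes, binned
    profiles, normalized auto- and cross-correlation, the autocorrelation
    amplitude periodicity statistic, period and phase estimation, and
    phase-aligned averaging of two-color data. Also includes dNSAF
    (distributed normalized spectral abundance factor) scoring and
    bait-versus-IgG fold-change filtering of co-immunoprecipitation spectral
    counts, image-level neurite interaction metrics (Otsu binarization,
    medial-axis fiber width, axon-dendrite bundling fraction, synapse density
    by puncta colocalization), and seeded synthetic-data generators that
    emulate all inputs so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
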