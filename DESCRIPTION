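Package: protophot
Title: Fiber Photometry and Behavioral Analysis for Nutrient Preference Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel (470 nm calcium-dependent /
    405 nm isosbestic) fiber photometry recorded during nutrient-conditioned
    two-bottle preference tasks in rodents. Covers lock-in demodulation of
    frequency-multiplexed LED signals, FFT-domain isosbestic correction,
    delta-F-over-F normalisation, first-lick-aligned trial segmentation with
    100-ms binned z-scores and epoch AUCs, lick microstructure and choice
    preference scoring, pose-track distance summaries, and an estimation
    statistics layer (BCa bootstrap confidence intervals and permutation
    p-values). A synthetic-session generator with ground truth makes every
    stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
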