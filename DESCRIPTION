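Package: popfam
Title: Population Coding Analysis of Visual Familiarity from Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for two-photon calcium-imaging studies of
    visual familiarity in mouse visual cortex. Converts raw and neuropil
    fluorescence into dF/F0 and thresholded spike events, builds
    surrogate-calibrated functional-connectivity graphs from binary
    coactivity, detects neuronal ensembles from high-coactivity frames
    with Jaccard/Ward clustering and surrogate-tested ensemble weights,
    and computes population statistics: Treves-Rolls population
    sparseness, natural-image selectivity, von Mises orientation tuning
    with full width at half maximum, population-vector overlap
    persistence with exponential decay fits, and post/pre plasticity
    ratios. Also reconstructs open-field position from force-plate
    sensors for stimulus-zone-preference scoring and summarises
    dendritic excitatory/inhibitory synapse tables. A synthetic-data
    generator with known ground truth (Poisson spiking, von Mises
    tuning, planted ensembles, calcium kernels, scripted trajectories)
    makes every stage testable without raw imaging data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
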