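Package: caplast
Title: Trial-Based Calcium Imaging and Intrinsic-Signal Plasticity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for sensory-evoked plasticity experiments
    combining two-photon calcium imaging and intrinsic optical signal
    mapping. Converts raw per-ROI fluorescence organised as trials into
    dF/F with baseline, noise and signal-to-noise estimates (separate
    cerebellar and barrel-cortex recipes), infers calcium events by
    thresholded AR(1) non-negative deconvolution (OASIS-style), builds
    evoked-event windows from per-frame event probabilities, quantifies
    pre/post plasticity as windowed AUC and amplitude with time-binned
    trajectories and per-animal normalisation, classifies rest versus
    active trials from movement traces, maps activation areas from
    reflectance stacks, and gates parametric versus non-parametric
    comparisons on Lilliefors normality. A ground-truthed synthetic-data
    generator covers every stage so the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    nortest,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
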