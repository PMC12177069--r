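Package: stimgait
Title: Personalized Deep Brain Stimulation Optimization for Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven optimization of deep brain stimulation
    (DBS) parameters targeting gait in Parkinson's disease. Implements a
    Walking Performance Index (WPI) built from spatiotemporal gait
    kinematics, Gaussian-process regression with a Matern kernel mapping
    stimulation settings (amplitude, frequency, pulse width) to WPI with a
    best/worst proposal policy, gait-cycle phase segmentation, wavelet power
    and wavelet-coherence spectral features locked to gait phases, artifact
    blanking and packet-loss exclusion for device-streamed field potentials,
    and mixed-effects biomarker regression with Benjamini-Hochberg
    correction. A fully seeded synthetic cohort generator provides
    kinematic streams, neural channels and trial manifests with known
    ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    lhs,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
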