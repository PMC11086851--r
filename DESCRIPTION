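Package: spineflex
Title: Classification of Low Back Pain Movement Phenotypes from
    Video-Derived Spine Flexion Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning two-dimensional pose-estimation keypoint
    trajectories (ankle, hip, neck) of repeated spine flexion into a
    spine-flexion angle waveform, segmenting the waveform into flexion
    repetitions with continuous-wavelet-transform peak detection, and
    extracting nine kinematic features alongside seven patient-reported
    outcome measures.  A two-stream feedforward classifier with batch
    normalisation separates movement-impairment (MI) from
    motor-control-impairment (MCI) non-specific low back pain, evaluated by
    stratified 5-fold cross-validation, exhaustive feature-subset search,
    per-feature ablation, and a binomial chance-level significance
    threshold.  Includes optical motion-capture criterion validation of the
    video-derived angle and a synthetic-cohort simulator so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
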