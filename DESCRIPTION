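Package: ieegmap
Title: Scalp-to-Intracranial EEG Translation for Interictal Spike Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps scalp EEG to concurrent intracranial (foramen-ovale) EEG
    with a conditional generative adversarial network whose generator is a
    1-D U-net over the time axis and whose objective couples the adversarial
    binary cross-entropy with an L2-distance regularizer.  Detects interictal
    epileptiform discharges (IEDs) from the estimated intracranial signal
    with a compact EEGNet-style convolutional classifier (batch normalization
    removed, max pooling throughout).  Includes clinical-EEG preprocessing
    (zero-phase band-pass and notch filtering, common average reference,
    channel selection, peak-centred segmentation), intra-subject and
    leave-one-subject-out evaluation protocols with average-vote ensembling,
    and a seeded generator of synthetic paired scalp/intracranial cohorts
    with annotated IEDs for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
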