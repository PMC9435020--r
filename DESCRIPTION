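Package: dmhbcg
Title: Ballistocardiogram Artifact Suppression for EEG Recorded in MRI by
    Dynamic Modeling of Heartbeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Suppresses the ballistocardiogram (BCG) artifact in
    electroencephalography (EEG) recorded inside an MRI scanner by dynamic
    modeling of heartbeats: each EEG sample is assigned cardiac coordinates
    (cycle, latency) from detected QRS complexes, the ballistocardiogram at
    that point is estimated as a weighted combination of EEG at the same
    latency in the cardiac cycles whose time-delay-embedded EKG dynamics are
    most similar, and the estimate is subtracted. Also provides a
    Pan-Tompkins style QRS detector, the optimal-basis-set (OBS) baseline,
    average artifact subtraction (AAS) for MRI gradient artifacts,
    steady-state visual evoked potential (SSVEP) evaluation tools (Morlet
    time-frequency analysis, noise normalization, ROC/AUC, bootstrap
    comparison), readers for BrainVision and EDF recordings, and a synthetic
    concurrent EEG-MRI generator with stored ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
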