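Package: qcmdlysis
Title: Detecting Phage-Induced Bacterial Lysis from Multi-Overtone QCM-D Dissipation Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quartz crystal microbalance with dissipation
    monitoring (QCM-D) assays of bacteriophage infection. Implements the
    overtone-spread statistic deltaD = DeltaD3 - DeltaD11, its normalization to
    the pre-injection growth maximum, smoothed second-derivative classification
    of lytic versus non-lytic outcomes, drop-fraction and fixed-timepoint
    readouts, and Welch group comparison. Ships closed-form acoustic physics
    (shear-wave penetration depth, Sauerbrey mass loading, a phenomenological
    overtone-dependent dissipation kernel, a coupled-resonance frequency term)
    and a seeded physics-informed simulator of multi-overtone QCM-D traces for
    phage-host screening experiments, so the full pipeline runs without
    instrument data. Includes a portable CSV trace dialect and an end-to-end
    screening report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
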