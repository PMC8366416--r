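Package: fpcnn
Title: Continuous Joint-Angle Decoding from Multichannel Surface EMG with a
    Channel-Wise Force-Pattern Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for continuous myoelectric decoding of forearm kinematics:
    a channel-wise convolutional regression model ("force-pattern" network)
    that maps 500 ms windows of 32-channel surface EMG envelopes to three
    joint angles (wrist flexion/extension, pronation/supination, hand
    grip/open), trained by Adam on mean squared error and scored by Pearson
    correlation under trial-wise five-fold cross-validation.  Includes the
    full preprocessing chain (rectification, integrated-EMG low-pass
    envelope, unit normalization, resampling to the kinematic rate),
    sliding-window dataset construction, freeze-convolution transfer
    learning for new-session recalibration, electrode-grid weight
    topography ("geometry") plots, conventional regression baselines with
    paired-test comparison, and a synthetic EMG/kinematics generator for
    end-to-end validation without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    signal,
    jsonlite,
    e1071,
    rpart,
    caret
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
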