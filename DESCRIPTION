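Package: myoreach
Title: Simulation of Combined EMG and Kinematic Control of a Transhumeral Prosthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless re-implementation of a myoelectric-plus-kinematic
    controller for a transhumeral prosthesis, driven by a synthetic subject in
    place of human participants. Six proximal surface EMG channels and the
    angular velocity and linear acceleration of a humerus-mounted inertial
    unit are conditioned into 50 ms feature frames; two time-delayed two-layer
    neural networks are trained to predict elbow flexion/extension and forearm
    pronation/supination; and a virtual target-reaching task with Fitts-law
    movement metrics (throughput, overshoot, path efficiency) evaluates
    open-loop and user-in-the-loop performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
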