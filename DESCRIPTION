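Package: spikewave
Title: Convolutional Spiking Neural Networks with At Most One Spike per Neuron
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates convolutional spiking neural networks in which every
    neuron emits at most one spike per stimulus and information is carried by
    time-to-first-spike rank order. Stimuli are represented as accumulative
    four-dimensional binary spike-wave tensors (time, feature, row, column)
    so that all time-steps can be processed with single tensor operations.
    Provides difference-of-Gaussians and Gabor filter banks with rank-order
    intensity-to-latency encoding, spiking convolution and pooling layers,
    winner-take-all competition with lateral inhibition, spike-timing-dependent
    plasticity (STDP) with a multiplicative stabilizer and reward-modulated
    STDP, a layer-wise training pipeline with reward/punish decision learning,
    a plain-text tensor interchange format, and a synthetic oriented-bar image
    generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
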