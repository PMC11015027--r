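Package: rsnn
Title: Recurrent Spiking Neural Networks that Learn Without Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulation of recurrent networks of leaky
    integrate-and-fire neurons with and without spike-frequency adaptation,
    trained in a learning-to-learn outer loop by surrogate-gradient
    backpropagation through time. Within an episode the synaptic weights are
    frozen and task adaptation happens purely through the network dynamics;
    the outer loop tunes the weights across a family of tasks. Ships four
    self-contained synthetic task families (sinusoid meta-regression, a
    two-link-arm forward model, a water-maze meta-reinforcement-learning
    environment with a clipped-surrogate policy objective, and one-shot
    pattern store/complete/delete), Dale's-law initialisation with sparse
    sign-preserving rewiring, internal-model probing, and a per-episode
    linear regression baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
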