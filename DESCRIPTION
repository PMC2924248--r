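Package: slowrl
Title: Hierarchical Slow Feature Analysis with Reward-Modulated Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-stage learning system for reinforcement learning on raw
    visual streams. A hierarchical network of slow feature analysis (SFA)
    nodes compresses grayscale image sequences, rendered from a simulated 2D
    world, into a few slowly varying features. Reward-modulated neural
    learners (a population-coded Q-learning ensemble and a policy-gradient
    neuron with nonlinear dendritic branches) are then trained on those
    features in closed loop. Includes the simulated environment with
    procedural sprite rendering, a Morris water-maze task and a
    variable-targets navigation task, baseline learners (hierarchical PCA
    features, point-neuron networks, hand-crafted state vectors), and an
    experiment harness producing learning curves and navigation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
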