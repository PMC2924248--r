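# slowrl

Reinforcement learning on raw visual streams via slow feature analysis.

Most reinforcement learning algorithms need a small, well-chosen state
space, while animals learn behavior from massive raw sensory input. This
package implements a generic two-stage learning system that closes that
gap in simulation: an unsupervised hierarchy of slow-feature-analysis
(SFA) nodes compresses a rendered visual stream (155×155 grayscale at
full scale, 24,025 pixels) into a few slowly varying features, and small
reward-modulated neural controllers then learn navigation tasks on those
features alone. It is aimed at computational neuroscientists and
reinforcement-learning researchers studying unsupervised state-space
formation.

## The model

**Slow feature analysis.** For a signal $x(t)$, find instantaneous
functions $g_j$ minimizing the slowness objective
$\Delta(y_j) = \langle \dot y_j^2\rangle$ under zero mean, unit variance
and decorrelation, solved exactly by a generalized eigenproblem of the
derivative covariance against the signal covariance (`sfa()`). Each
hierarchy node (`sfa_node()`) chains noise injection, linear SFA,
quadratic expansion and a second linear SFA, so a four-layer converging
network of weight-shared nodes (`sfa_hierarchy()`) computes high-degree
polynomial features of image patches, trained layer by layer on random-
walk stimulus streams from the built-in 2D world (agent fish with two
identities, cross and disk objects, procedural anti-aliased rendering).

**Reward-based control.** A population of linear neurons with preferred
directions implements neural Q-learning via a population-vector readout,
a Gaussian action profile, eligibility traces and a TD error
(`q_population()`, `run_watermaze()`); a policy-gradient neuron with
nonlinear dendritic branches
($u = \sum_k q_k \tanh(w_k x) + b + \xi$, node-perturbation updates
$\Delta\theta \propto (R-\bar R)\,\xi\,\partial u/\partial\theta$)
controls speed and angular velocity in a variable-targets task
(`branch_neuron()`, `run_variable_targets()`). Baselines: hierarchical
PCA features, two-layer point-neuron networks, and a hand-crafted state
vector.

## Worked example

Train a smoke-scale hierarchy (40×40 input, three layers) on a water-maze
stream and inspect what it learned:

```r
library(slowrl)
wc  <- world_config(resolution = 40, n_objects = 0)
cfg <- scaled_hierarchy_config("smoke")
h   <- sfa_hierarchy(function(n, seed)
         generate_training_stream(n, wc, "watermaze", seed = seed),
       cfg, seed = 11)
print(h)
#> Hierarchical SFA network: 40 x 40 input -> 24 features
#>   layer 1: 9 x 9 grid, field 8, overlap 4, node 64 -> 12
#>   layer 2: 4 x 4 grid, field 3, overlap 1, node 108 -> 12
#>   layer 3: 1 x 1 grid, field 4, overlap 0, node 192 -> 24
```

The slowest top-level outputs track the agent's position: on a held-out
stream, the best correlation between a top component and the agent's
x-position exceeds 0.9 when position is the stream's only slow latent.
Training the Q-learning agent on the 16 slowest features then learns the
water maze:

```r
res <- run_watermaze(h, seeds = 1:10, n_episodes = 100,
                     n_features = 16, world_cfg = wc)
print(res)
#> water-maze run: 100 episodes x 10 seeds
#>   mean latency, first 10 episodes: 335.9 steps
#>   mean latency, last 10 episodes:  222.9 steps
#>   plateau episode: 31
```

Escape latency (steps to the invisible platform) falls by roughly a
third within the first few dozen episodes and the 10-seed mean curve
settles around episode 31 — place-learning-like acquisition from raw
pixels at a deliberately tiny 40-pixel scale. `navigation_map(res$agents[[1]], h, world_cfg = wc)` returns
the greedy movement direction on a probe grid; near the goal the vectors
point at it.

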