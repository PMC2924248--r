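---
title: "Slow features and reward-modulated control: the methods behind slowrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow features and reward-modulated control: the methods behind slowrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(slowrl)
```

## The problem

Reinforcement learning algorithms are only practical when the state space
is small, yet animals learn behavior from massive raw sensory streams.
`slowrl` implements a generic two-stage answer: an unsupervised stage that
compresses a raw visual stream into a handful of slowly varying features,
and a reward-driven stage of small neural controllers that learn a policy
on those features alone. The package contains everything needed to study
this closed loop: a simulated 2D world rendered to grayscale images, the
hierarchical slow-feature network, two reward-modulated learners, and the
experiment harness that produces learning curves and baselines.

## Slow feature analysis

Given a multidimensional signal $x(t)$, SFA finds instantaneous functions
$g_j$ whose outputs $y_j(t) = g_j(x(t))$ minimize the temporal slowness
objective

$$\Delta(y_j) = \langle \dot y_j^2 \rangle_t$$

subject to zero mean, unit variance and mutual decorrelation. The
constraints exclude the constant solution and force different components
to code different aspects; they also order components by slowness, the
first being slowest. Because the $g_j$ are instantaneous, slowness cannot
come from low-pass filtering — it must be extracted structurally from the
input.

For a finite-dimensional function space the optimum is found exactly by an
eigenvector method. `sfa()` centers the signal, estimates the signal
covariance $C$ and the second moment $\dot C$ of the forward differences
$x(t{+}1) - x(t)$, whitens with $C^{-1/2}$ and takes the smallest
eigenvectors of the whitened $\dot C$. Numerical choices:

* **Derivative estimator.** Forward differences, giving $T-1$ derivative
  samples; the simplest consistent discretization and standard practice.
* **Regularization.** $\varepsilon I$ with
  $\varepsilon = 10^{-10}\,\mathrm{tr}(C)/d$ is added to $C$ before
  eigendecomposition, guarding rank deficiency; directions with
  eigenvalues below $10^{-12}$ of the largest are dropped (with a warning
  if that truncates the requested output dimension).
* **Sign convention.** Each component's largest-magnitude loading is made
  positive; SFA components are sign-ambiguous and deterministic signs
  keep runs reproducible.

A quadratic function space is obtained by explicit expansion:
`quadratic_expand()` appends all monomials $x_i x_j$, $i \le j$ (original
channels first, then pairs in row-major order), taking $d$ channels to
$d + d(d+1)/2$. Linear SFA on the expanded signal equals SFA over
polynomials of degree two.

## One node, one layer, one network

A hierarchy node (`sfa_node()`) chains: additive white Gaussian noise
(variance $10^{-4}$ by default) to avoid singular covariances; linear SFA
for a first dimensionality reduction; quadratic expansion; a second
linear SFA; and clipping at $\pm 4$. Noise and clipping are technical
safeguards — the noise is applied only while accumulating training
statistics, never at apply time, so a trained node (and hence the whole
control loop) is deterministic. The clip bound and noise variance are
tunable; both typically have no effect on performance.

`sfa_hierarchy()` tiles such nodes into a converging, topographic,
feed-forward network. The full-scale architecture on 155×155 images has
four layers: 30×30 nodes with 10×10-pixel receptive fields overlapping by
5; 14×14 nodes seeing 4×4 predecessors (overlap 2); 6×6 nodes seeing 4×4
(overlap 2); and one top node seeing all 6×6, with first-stage dimensions
32/32/42/52, per-node outputs 32/32/32/64. `plan_geometry()` checks the
tiling identity $(g-1)s + f = p$ exactly and refuses configurations that
do not cover the previous layer.

Layers are trained sequentially bottom-up with weight sharing: one node
per layer is fitted on patches gathered from every grid location (a
location's patches are differenced along its own time axis) and
replicated across the layer. Training streams are regenerated per layer
group with identical random-walk parameters: 50,000 frames for the two
lower layers and 200,000 for the upper layers at full scale. The PCA
variant (`variant = "pca"`) keeps the identical pipeline, tiling,
expansion and dimensions and changes only the ranking criterion
(explained variance, descending) — isolating slowness as the single
difference under study. PCA stage outputs are standardized to unit
variance: raw principal components have unbounded scale, which would
turn the clipping safeguard into the dominant nonlinearity and confound
the comparison.

### Scaled profiles

Full-scale training is a cluster-sized computation. Two scaled profiles
preserve every architectural ratio (converging overlapping fields, weight
sharing, per-node expansion) at interactive sizes, and all code paths are
shared between scales:

* `scaled_hierarchy_config("smoke")` — 40 px input, three layers
  (grids 9/4/1), 2,000 + 3,000 training frames; trains in seconds.
* `scaled_hierarchy_config("desk")` — 63 px input, three layers
  (grids 10/4/1, top output 32), 10,000 frames per layer group; this is
  the profile used by the package's reproduction script.

## The simulated world

The environment is a square arena (bounds $[-1,1]^2$ by default; the
standard radii 0.4 and 0.2 are natural fractions of this box) with an
agent — an oriented procedural fish sprite whose two identities differ by
a stripe pattern — and, for the variable-targets setting, a cross and a
disk. Rendering is anti-aliased so pixel intensities vary continuously
with pose; that temporal continuity is precisely the statistical property
slowness learning requires. The unsupervised training streams follow a
bounded random walk: per step, each velocity component receives a uniform
perturbation of at most 0.01 and is clamped to 0.06 in magnitude
(0.01/0.04 for the agent's angular velocity); entities bounce off the
walls and off each other by radius; the agent identity flips with
probability 0.002 per step.

What the generator emulates: smooth bounded trajectories whose slow
latents are positions, orientation and identity — exactly the variables
the tasks need. What it does not emulate: natural image statistics,
occlusion, lighting, or a first-person perspective; passing tests
therefore demonstrate the mechanism on clean synthetic streams, not
performance on natural video.

### Tasks

**Water maze.** A single fish type, never rotated, invisible fixed target.
One directional command moves the agent a fixed step; the position is
hard-clamped to the arena. Rewards are sparse: +1 on reaching the goal,
−0.1 when the step had to be clamped (a wall hit), 0 otherwise. The
constants (target (0.5, 0.5), goal radius 0.25, step 0.05, budget 500
steps) are package defaults chosen to make the scaled task well-posed:
the goal is about 5% of the arena area (a realistic platform-to-pool
ratio), an episode allows a dozen arena crossings, and a random policy
discovers the goal in roughly a third of episodes — enough early goal
events that a 100-episode study is informative. All constants are
configurable and recorded in run manifests.

**Variable targets.** Two fish identities, a cross and a disk placed
afresh each episode; identity A's target is the cross, B's the disk, and
the other object is a pure distractor. The controller emits a speed
$v \in (0,1)$ and an angular command $\omega \in (-1,1)$; the heading
advances by $c_\omega \omega$ and the position by $c_v v$ along the
heading. The package defaults are $c_v = 0.05$ and $c_\omega = 2$: the
agent can reorient within a step or two. The angular gain matters for
learnability at reduced budgets — perturbation learning extracts reward
information only from states where output noise can flip the reward, and
that band of states scales with the angular gain; pilot runs with a gain
an order of magnitude smaller showed no measurable learning within any
desk-scale budget. At the walls the trajectory is mirrored — position *and* heading
component reflect, as in a billiard — with a clamp mode available for the
control experiment; reflecting the heading is what keeps agents from
sticking in corners. The reward is +1 when the Euclidean distance to the
target strictly decreased, −1 otherwise; a tie (e.g. zero speed) counts
as "not closer". Episodes end within the goal radius (0.25) or after 200
steps at desk scale.

## Reward-based learners

### Population Q-learning

The Q-function over movement directions is carried by $M = 36$ linear,
bias-free neurons with uniformly spaced preferred directions $\phi_a$:
$Q_a = w_a \cdot y$. The greedy action is the angle of the population
vector $\sum_a Q_a (\cos\phi_a, \sin\phi_a)$ (drawn uniformly at random
when the resultant cancels below $10^{-12}$); with probability
$\varepsilon = 0.1$ a uniform random direction is taken instead. A
Gaussian activity profile ($\sigma = 1.5 \cdot 2\pi/M$) around the chosen
action is enforced in the ensemble; the eligibility trace accumulates the
normalized profile as the postsynaptic factor,
$e \leftarrow \gamma\lambda e + \bar a \otimes y$, and the TD error
$\delta = R + \gamma Q(s', a^*) - Q(s, a_\text{chosen})$ gates the
weight update $\Delta w = \eta_t\, \delta\, e$ with the decaying rate
$\eta_t = \eta_0/(1 + t/\tau)$.

Three details are the package's own, all needed for stability with
linear function approximation on a *global* (non-localized) feature
basis. $Q(s, a_\text{chosen})$ is read out as the normalized-profile
interpolation of the population Q-values, making the trace the exact
gradient of that readout. The bootstrap value $Q(s', a^*)$ is the same
profile readout at the next state's population-vector direction — the
value the population itself assigns to acting greedily — rather than the
raw maximum over all neurons; with slow-feature bases (which, unlike
place cells, are global functions of position) the raw maximum is
upward-biased and we found the update loop diverges for every usable
learning rate. Finally, the trace is reset on exploratory actions (the
Watkins convention). Defaults $\eta_0 = 0.3$, $\tau = 1200$,
$\gamma = 0.95$, $\lambda = 0.9$, $\varepsilon = 0.1$ were fixed by
pilot stability runs at the smoke scale — the original hyperparameter
listing is not part of the package's sources, so these stand as
documented package defaults.

### Policy-gradient neurons with dendritic branches

For the variable-targets task each control variable is produced by one
neuron with $K = 10$ nonlinear branches: branch $k$ computes
$b_k = \tanh(w_k \cdot x)$, the soma sums
$u = \sum_k q_k b_k + b_0 + \xi$ with uniform exploration noise
$\xi \in [-0.5, 0.5]$ drawn fresh each step, and the output is
$y = \tanh(u)$ (angular) or the logistic $\sigma(u)$ (speed). Both the
synaptic weights and the branch-soma couplings are plastic. The update
rules perform node-perturbation gradient ascent on the reward:

$$\Delta w_{kj} = \eta_w (R - \bar R)\,\xi\, q_k (1 - b_k^2)\, x_j,
\qquad
\Delta q_k = \eta_q (R - \bar R)\,\xi\, b_k,
\qquad
\Delta b_0 = \eta_b (R - \bar R)\,\xi,$$

with $\bar R$ an exponential low-pass of the reward. These forms were
re-derived from the neuron model (each parameter is credited through its
influence $\partial u/\partial\theta$ on the perturbed somatic input);
their correctness is defined operationally: the test suite checks that
the expected update direction matches a finite-difference gradient of the
expected reward on a battery of small random instances (cosine
similarity > 0.9). No eligibility traces are used. Initial parameters are
drawn with spread 0.7 rather than zeros — exactly zero couplings would
freeze the synaptic gradient, which is proportional to $q_k$ — and the
default learning rates $\eta_w = \eta_q = \eta_b = 0.1$ and baseline
time constant 50 were fixed by pilot runs at the smoke scale (the
original hyperparameter listing is not part of the package's sources).

Batch training runs 100 parallel traces: one time step is simulated in
every trace, the per-trace updates are averaged and applied once, and a
finished trace is re-initialized while the others continue. Each trace
carries its own reward baseline $\bar R_i$ (time constant 50 steps): the
low-pass reward baseline is a property of a reward *stream*,
and in batch mode each trace is its own stream; a shared baseline would
re-introduce cross-trace state variance into every update. The simpler
point-neuron baseline (`simple_network()`, 50 hidden units per control
variable) uses the same perturbation rule independently per neuron.

### What scaled runs can and cannot show

Perturbation learning on a binary ±1 reward extracts a fraction of a bit
per step; at full scale the original experiments run for millions of
environment steps. The package's scaled comparisons therefore measure the
*early* learning phase at matched budgets (hundreds of thousands of
steps) and compare arms by improvement and final smoothed reward at equal
budget — the qualitative orderings (slow features usable, raw-PCA
features not; branch neurons faster than point-neuron networks;
hand-crafted state vector comparable to slow features) are expected to
emerge in this phase, while absolute converged reward levels are out of
desk-scale reach by design. The linear-decodability probe
(`latent_probe_r2()`) supplements the control runs: position is linearly
decodable from slow features but not from hierarchical-PCA features of
the same stream, which is the representational reason behind the control
orderings.

## Experiment harness

`run_watermaze()` trains the Q agent on the 16 slowest features over
independent episode sets (10 seeds by default), returning per-episode
escape latencies, the mean ± SD curve, the trained agents and a manifest
(config, seeds, package version) sufficient to reproduce the curve
bit-for-bit. Convergence is operationalized by `plateau_episode()`: the
first episode from which the 10-episode running mean stays within 20% of
the final 20-episode mean. `navigation_map()` probes the trained greedy
policy on a position grid. `run_variable_targets()` provides the batch
policy-gradient training with either hierarchy features or the explicit
state vector (components standardized to approximately unit variance
under the initial-state distribution, since the sigmoids need bounded
inputs), and `feature_count_sweep()` repeats it over feature counts
{16, 22, 28, 32, 64}. `smooth_curve()` implements the block-mean
smoothing conventions; trailing partial blocks are dropped.

## Reproduction script

`scripts/acceptance.R` recomputes, from one root seed: the tiling
arithmetic of the full-scale architecture; the empirical velocity caps
and identity-switch rate over a 100,000-step random walk; and the plateau
episode of the scaled water-maze experiment (desk profile: 63×63 input,
three layers, 10,000 training frames, 10 seeds × 100 episodes). Problem
sizes are the desk-scale profile's; every stochastic stage derives its
seed from the root via `derive_seeds()`.

## Known limitations

* The hierarchy is feed-forward only; no recurrence or feedback.
* Sprites are procedural; any visually distinguishable, orientation-
  bearing sprites satisfy the method, but results on natural imagery are
  not implied.
* Perturbation learning at desk scale shows early-phase trends, not
  converged policies (see above).
* Online/biologically-plausible SFA learning rules and first-person
  rendering are out of scope.
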