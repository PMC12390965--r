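---
title: "Reward-optimized stochastic release plasticity: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-optimized stochastic release plasticity: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsrp)
```

## The model

Each synapse is modeled as a Bernoulli distribution over transmission: on a
given trial the synapse either releases ($\theta = 1$) or fails
($\theta = 0$), with release probability $\rho$. The network realized from
one release sample $\boldsymbol\theta$ interacts with its task and earns a
single global scalar reward $R(\boldsymbol\theta)$. Learning maximizes the
expected reward

$$J(\boldsymbol\rho) = \mathbb{E}_{\boldsymbol\theta \sim
B(\boldsymbol\rho)}\left[R(\boldsymbol\theta)\right]$$

by ascent on $\boldsymbol\rho$ itself. The gradient is available without
differentiating the network, via the score function of the Bernoulli
likelihood:

$$\nabla_\rho J = \mathbb{E}\left[\frac{\theta - \rho}{\rho(1-\rho)}\,
R(\boldsymbol\theta)\right],$$

and because synapses are independent, the Fisher information matrix is
diagonal with entries $1/(\rho(1-\rho))$. Preconditioning the score
gradient with the inverse Fisher matrix (the natural gradient) cancels the
variance-inflating denominator exactly, leaving the remarkably simple
plasticity rule implemented by `rsrp_update()`:

$$\Delta\rho = \frac{\eta}{N}\sum_{i=1}^{N} (\theta_i - \rho)\,R_i,
\qquad
\rho \leftarrow \mathrm{clip}(\rho + \Delta\rho,\ \epsilon,\ 1-\epsilon).$$

The update is local (presynaptic release sample, own probability) apart
from the global reward, and the clipping threshold $\epsilon$ keeps every
probability inside $[\epsilon, 1-\epsilon]$ so the Fisher factor stays
finite. The algebraic identity between the clipped update direction and
$\eta F^{-1}\hat\nabla J$ is asserted exactly (to $10^{-12}$) in the test
suite, as is the agreement of the Monte-Carlo estimator with brute-force
enumeration of all $2^K$ release patterns on tabulated reward functions
(`enumerate_reward()` is the oracle).

`hedonistic_update()` implements the earlier sigmoid-parameterized rule
($p = \sigma(q)$, eligibility $e = \theta - p$) for comparison. Its
original formulation accumulates the eligibility-reward product over time
steps; we sum over release samples instead, mirroring the summation
structure of the main rule, and treat the two as directly comparable
baselines rather than claiming equivalence.

## Reward regularization

Raw task rewards enter the rule only after a configurable transform:

* **Centered rank** (`centered_rank()`, the default):
  $R_i' = -\tfrac12 + \tfrac1N\sum_j \delta(R_i > R_j)$. Only the ordering
  of rewards survives, which makes the rule invariant to monotone reward
  rescaling and robust to heavy-tailed returns. Ties share a value; with
  all rewards tied every $R_i' = -\tfrac12$ and the update has zero mean.
* **Zero mean** (`zero_mean_transform()`): subtracts the running mean of
  all previously seen raw rewards. The first batch passes through
  unchanged (baseline 0); a flag switches to within-batch centering.
* **Identity**: raw rewards, the no-regularization ablation.

For classification, three sparse reward signals are provided: accuracy
(optionally top-$k$), negative mean cross-entropy of the softmax (with
max-subtraction for stability), and *soft recall* — the mean reciprocal
rank of the true class in the descending score ordering, normalized by the
batch size. Every instance yields exactly one prediction, so the batch
size plays the role of the true-plus-false-positive count and a perfect
batch earns exactly 1. Rank ties are broken toward the smaller class
index after a stable descending sort: degenerate, but deterministic.

## Network architectures

All weights are realized from release samples as $W = g\,\theta$ with a
per-layer gain $g = c/\sqrt{\mathrm{fan~in}}$, so weight matrices are
elementwise nonnegative. Inhibition enters only through the sign flip
applied to the second half of each layer's activations; each hidden layer
is split into equal excitatory and inhibitory populations. Inputs are
balanced by concatenating each feature vector with its negation, so every
input current sums to zero across the on/off pair. There are no bias terms
anywhere.

The classification network is a rectifier MLP in this EI form; spiking is
reserved for reinforcement learning, where the policy is a recurrent layer
of discrete-time leaky integrate-and-fire neurons (exponential synaptic
current, decay $\alpha$; leaky membrane, decay $\beta$; threshold, reset)
read out by a non-spiking leaky integrator whose argmax selects the
action. One release sample per synapse is drawn at the start of each
episode and held fixed for all of its timesteps; training rollouts are
stochastic in the weights, while the logged evaluation uses the expected
weights $g\rho$ as a deterministic analog network (as learning drives the
probabilities toward 0 and 1, sampled and expected evaluation converge; a
flag restores sampled evaluation).

### Constants the dynamics need (and why)

The discrete-time LIF constants are design choices, made once and exposed
through `lif_params()`:

* $\beta = 0.9$, $\alpha = 0.5$, threshold 1, reset 0 — standard
  discrete-time surrogate settings; one LIF step per environment step.
* **Membrane floor** `v_min = -1`. An unbounded LIF membrane integrates
  sustained inhibition arbitrarily far below reset, after which the neuron
  needs many steps to recover when its input changes sign. For closed-loop
  control this hysteresis is fatal: a hand-wired spiking implementation of
  a known-good balancing law survives only ~38 steps without the floor and
  the full 500 with it. The floor plays the role of an inhibitory reversal
  potential and is applied after threshold and reset.
* Readout decay 0.5 — short enough that the integrator can change its mind
  within a few steps of a spike-rate reversal.
* Per-layer gain scales $c = (2, 1, 2)$ for input, recurrent and readout
  connections. The weaker recurrent scale keeps the recurrent drive from
  swamping the input drive at mid-range probabilities, where half of all
  recurrent synapses transmit on average.
* Observation scaling `cartpole_obs_scale()` = $(1, 1, 0.1, 0.3)$: the
  pole angle and angular velocity are amplified so the variables that must
  be regulated fastest dominate the input currents; raw cart position
  (range $\pm 2.4$ m) would otherwise bury the pole angle (range
  $\pm 0.21$ rad).

### Initialization

Release probabilities initialize at mean 0.5 — the maximum-entropy
Bernoulli — with uniform jitter of half-width 0.45 per synapse
(`init_jitter`). The jitter matters more than it looks: at the exactly
constant initialization all hidden neurons are interchangeable, the
expected network is perfectly balanced and therefore silent, and no
individual input or recurrent synapse has a first-order effect on the
expected reward — measured on the cart-pole task, the largest per-synapse
correlation z-score over 4,096 recurrent synapses is ~3 at a population of
20,000, i.e. indistinguishable from noise, and training stalls
indefinitely. Heterogeneous initial probabilities give each hidden neuron
a stable tuning that persists across release samples, which is what lets
the readout — and then everything else — pick up gradient signal
(largest z-scores ~10 under jitter). `release_probs()` itself keeps the
deterministic constant constructor as its default; the network builders
opt into jitter.

## Training loops

Both trainers alternate the same two stages: *population evaluation* (draw
$N$ release-sample sets, earn one scalar reward each) and *plasticity
optimization* (transform rewards, update every trainable layer, clip).

For reinforcement learning each sample runs one full cart-pole episode;
the bundled simulator uses the standard constants (gravity 9.8, cart mass
1.0, pole mass 0.1, half-length 0.5, force $\pm 10$ N, $dt = 0.02$ s,
semi-implicit Euler with position updated by the old velocity), reward +1
per step, termination at $|x| > 2.4$ m, $|\theta| > 12^\circ$ (strict
comparisons) or 500 steps. Episode seeds derive deterministically from
(master seed, iteration, sample index), so populations are reproducible
and independent of evaluation order. The inner loop over population
episodes is compiled (Rcpp); the pure-R reference path computes the same
trajectories and the test suite asserts the two agree episode for
episode.

For classification each sample is scored on a data batch — either one
batch shared by the whole population or a fresh batch per sample, drawn
without replacement within an epoch. Training is driven by the sparse
batch reward alone; no per-instance error signal exists anywhere.

Two named presets fix the problem sizes used throughout the package:
`"full"` (hidden 256, $N = 10{,}240$, $\eta = 0.15$, $\epsilon = 0.001$,
100 iterations) and `"desk"` (hidden 64, $N = 512$, $\eta = 0.7$,
otherwise identical), the scale at which every shipped experiment runs in
minutes on one CPU. The desk learning rate is deliberately larger: with a
20-fold smaller population each gradient estimate is noisier, and crossing
the same distance in probability space within 100 iterations takes fewer,
larger steps. Learning rates are treated as per-configuration tuning
parameters throughout. At the desk scale, training halts early once the
deterministic evaluation reaches the environment's return cap
(`stop_at_return = 500`); all five desk seeds reach the cap within 100
iterations. The matching classification preset
(`"desk_classification"`: hidden 32, 64 release samples of 16-instance
batches, $\eta = 1.2$, 400 updates) reaches ~0.85 held-out accuracy on
the synthetic digit task.

Momentum and Adam exist only as reserved configuration hooks; plain
stochastic updates are the implemented (and sufficient) optimizer.

## Synthetic data

`make_digit_patterns()` draws noise-corrupted copies of ten fixed 8×8
binary glyphs — a desk-scale stand-in for handwritten digits chosen so
full training sweeps stay in the minutes range; an IDX reader
(`read_idx_dataset()`) accepts the standard digit-image container when
real data are at hand. The default pixel-flip probability (0.1) leaves
the task comfortably learnable by a centroid classifier while giving the
plasticity rule a realistic noise floor. `make_cluster_classification()`
places Gaussian clusters at scaled simplex vertices, spanning chance
(separation 0) to perfect separability. `make_target_pattern_reward()`
tabulates the Hamming-proximity bandit used for parameter recovery, and
`enumerate_reward()` computes exact expected rewards and gradients over
all $2^K$ patterns ($K \le 12$).

What the generators do *not* emulate: correlated pixel noise, class
imbalance, within-class style variation, or distribution shift between
training and evaluation. Tests passing on these generators therefore
certify the learning machinery — estimator correctness, convergence,
regularization ordering, entropy contraction — not performance on any
real dataset.

## Numerical choices and degenerate inputs

* Reward sums accumulate in double precision via matrix products; the
  natural-gradient identity is asserted to $10^{-12}$.
* Probabilities are clipped to $[\epsilon, 1-\epsilon]$ with
  $\epsilon = 0.001$ everywhere (the reinforcement-learning value; no
  separate classification value is defined, so the same one is used).
* With $N = 1$, the centered rank of any reward is $-\tfrac12$: the update
  has zero mean and the algorithm cannot learn — observable in the
  sampling-size study, and the reason the synaptic sampling size is the
  one critical hyperparameter.
* Score ties in classification rewards and action ties in the argmax
  readout resolve to the smallest index, making every trajectory
  deterministic given its seeds.
* A zero learning rate is accepted as an exact null update (a useful
  control); stepping a terminated episode is an error rather than a
  silent reset.
* Checkpoints serialize probabilities as JSON with 17 significant digits,
  the shortest representation that round-trips IEEE doubles bit-exactly.

## Known limitations

* The sampled-weight evaluation mode is exposed but the reported curves
  use expected weights; early in training the two can differ substantially
  while entropy is high.
* Only diagonal (independent-synapse) Fisher preconditioning is supported;
  correlated release is out of scope.
* The desk-scale cart-pole result depends on the architecture constants
  described above; they were chosen for that task family and documented,
  not derived from first principles.
* Continuous-action readout (tanh of the integrator) is stubbed for
  external environments but untested here; the bundled task is discrete.
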