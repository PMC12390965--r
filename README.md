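# rsrp — reward-optimized stochastic release plasticity

Biological synapses transmit stochastically: a presynaptic spike releases
vesicles only with some probability. This package treats that release
probability itself as the learned parameter. Each synapse is a Bernoulli
distribution with parameter ρ; a network is *realized* by sampling one
binary release pattern θ per trial, interacting with a task, and earning a
single global scalar reward R(θ). Learning is natural-gradient ascent on
the expected reward J(ρ) = E[R(θ)]: because the Fisher information of
independent Bernoulli synapses is diagonal with entries 1/(ρ(1−ρ)), the
Fisher-preconditioned score-function gradient collapses to the local
plasticity rule

    Δρ = (η / N) · Σᵢ (θᵢ − ρ) · Rᵢ ,   ρ ← clip(ρ + Δρ, ε, 1 − ε)

— a reward-modulated, backpropagation-free update requiring nothing from
the network but its samples and its rewards. The package is aimed at
computational-neuroscience and bio-plausible-learning work: it provides
the rule and its estimator algebra, centered-rank and zero-mean reward
regularization, excitatory–inhibitory balanced architectures obeying
Dale's law (nonnegative weights, sign-flipped inhibitory activations,
balanced `concat(x, −x)` input coding), a recurrent leaky
integrate-and-fire spiking policy network with a frozen-reservoir variant,
a bundled cart-pole simulator, sparse-reward classification on synthetic
digit data, an exact 2^K enumeration oracle for gradient checks, and a
sigmoid-parameterized hedonistic-synapse baseline.

## Worked example: balancing a pole with stochastic synapses

```r
library(rsrp)

cfg <- rsrp_preset("desk", seed = 1)   # hidden 64, N = 512 episodes/update
fit <- train_rl(cfg, verbose = TRUE)
#> iter   5: population mean 23.3, eval 16.0
#> iter  20: population mean 49.7, eval 115.8
#> iter  40: population mean 104.8, eval 203.2
#> iter  60: population mean 184.2, eval 244.2
#> iter  75: population mean 263.9, eval 476.8
#> iter  85: population mean 303.7, eval 500.0
fit$final_eval
#> [1] 500
```

Each iteration draws 512 release-sample networks, runs one full cart-pole
episode per network, rank-transforms the 512 episodic returns and applies
the plasticity rule to all three connection matrices. `eval` is the return
of the deterministic expected-weight network (weights g·ρ) on fresh
episodes; 500 is the episode cap, i.e. the pole never falls. Training
stops as soon as the evaluation reaches the cap (here after 85
iterations, about 20 s).

The same rule trains a classifier from a sparse batch-level reward alone:

```r
digits <- make_digit_patterns(50, pixel_noise = 0.1, seed = 11)
held_out <- make_digit_patterns(50, pixel_noise = 0.1, seed = 99)
cls <- train_classification(rsrp_preset("desk_classification", seed = 1),
                            digits, eval_data = held_out)
cls$final_eval          # held-out accuracy after 400 sparse-reward updates
#> [1] 0.85
tail(cls$log$entropy_layer1, 1) / cls$log$entropy_layer1[1]
#> [1] 0.5223743
```

The entropy ratio shows the release distribution consolidating: roughly
half of the first layer's initial synaptic uncertainty (in nats) is gone
by the end of training.

A thin command-line wrapper over these functions ships in
`inst/cli/rsrp.R` (`train-rl`, `train-cls`, `sweep` subcommands).

## Package layout

| Where | What |
|---|---|
| `R/release.R` | Bernoulli release model, plasticity rule, estimators, entropy, hedonistic baseline |
| `R/rewards.R` | centered-rank / zero-mean transforms, classification rewards |
| `R/models.R` | EI layers, balanced input, LIF dynamics, recurrent spiking policy |
| `R/cartpole.R` | bundled cart-pole environment and episode runner |
| `R/train.R` | population evaluation, RL/classification/bandit trainers, presets, sampling sweep |
| `R/synthetic.R` | digit/cluster generators, tabulated rewards, enumeration oracle |
| `R/idx.R`, `R/checkpoint.R` | IDX digit-file reader/writer, JSON checkpoints |
| `src/rollout.cpp` | compiled population rollout (verified against the R reference) |
| `vignettes/` | methods vignette: model, design choices, limitations |
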