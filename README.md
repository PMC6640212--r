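# spikewave

Simulation of convolutional spiking neural networks in which **every neuron
emits at most one spike per stimulus** and information is carried by
**time-to-first-spike rank order**. The package is aimed at computational
neuroscientists and neuromorphic-computing researchers who want a compact,
fully inspectable implementation of this network family — retina-like
DoG/Gabor front ends, spiking convolution and pooling, winner-take-all
competition, STDP and reward-modulated STDP — in plain R, at desk scale.

## The model

A stimulus is a grid of `F × H × W` neurons, each firing once at a discrete
time-step `T[f,r,c] ∈ {0, …, T_max − 1}` or never (`∞`). The package's
central data structure is the **accumulative spike-wave tensor** `S` of
shape `T_max × F × H × W`:

```
S[t, f, r, c] = 0  if t < T[f,r,c],   1 otherwise
```

A spike is redundantly repeated at every later step, so one tensor
operation processes *all* time-steps simultaneously: convolving `S` with a
weight kernel yields the accumulated membrane potential
`P[t, f, r, c]` of every neuron at every step in a single pass, and a
threshold applied to `P` yields the next layer's spike wave, again in
accumulative form.

Learning uses the simplified STDP rule for single-spike latency codes:
for a winning post-synaptic neuron `i` and each synapse from pre-synaptic
neuron `j`,

```
ΔW[i,j] = A⁺ · (W − LB)(UB − W)   if T_j ≤ T_i     (potentiation)
ΔW[i,j] = A⁻ · (W − LB)(UB − W)   if T_j > T_i     (depression)
```

where `(W − LB)(UB − W)` is a multiplicative stabilizer making the weight
bounds fixed points (optionally replaced by hard clamping). Winners are
selected by earliest spike, then largest potential, with lateral inhibition
around each winner and per-winner feature suppression. Reward-modulated
STDP (R-STDP) is the same machinery with a paired, sign-negated rule:
correct decisions trigger the STDP rule, wrong decisions the anti-STDP
rule.

## Worked example

The spike-wave algebra:

```r
library(spikewave)
times <- array(c(0L, 2L, NA, 1L), dim = c(1, 2, 2))  # one 2x2 feature map
w <- spike_times_to_wave(times, t_max = 4)
w[, 1, 1, 1]
#> [1] 1 1 1 1        # spiked at step 0: on from the start
w[, 1, 2, 1]
#> [1] 0 0 1 1        # spiked at step 2
wave_to_spike_times(w)[1, , ]
#>      [,1] [,2]
#> [1,]    0   NA     # NA = the neuron never spiked
#> [2,]    2    1
```

The full desk-scale experiment — synthetic two-class oriented-bar images,
six-channel DoG encoding into 15 time-steps, a three-stage network
(S1→C1→S2→C2→S3→global decision) trained layer-wise with STDP and then
R-STDP:

```r
res <- run_experiment(seed = 1, verbose = TRUE)
#> epoch  1: correct 36 wrong 24 silent 0 (0.600)
#> epoch  2: correct 60 wrong 0 silent 0 (1.000)
evaluate_network(res$net, res$dataset)
#> correct 60 / wrong 0 / silent 0 (n = 60, accuracy 1.000)
```

`correct`/`wrong` count decisions (the label block of the most salient
decision-layer neuron) against the ground truth; `silent` counts stimuli
that elicited no decision-layer spike at all.

The classic selectivity result — a winner-take-all STDP layer locking onto
a spatio-temporal spike pattern recurring among noise:

```r
sel <- selectivity_experiment(seed = 1)
sel$cosine
#> [1] 0.9           # cosine between a learned weight vector and the
                    # pattern's binary indicator
```

A command-line front end for dataset generation, training, evaluation and
tensor-file conversion is installed under `inst/cli/spikewave-cli.R`.

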