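---
title: "Single-spike convolutional networks: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-spike convolutional networks: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikewave)
```

## The model and its assumptions

`spikewave` simulates feedforward convolutional spiking networks under
three hard assumptions:

* **at most one spike per neuron per stimulus** — the neuron model is a
  non-leaky integrate-and-fire unit that stays "on" after its first
  threshold crossing;
* **time-to-first-spike coding** — all information is carried by *when*
  a neuron first fires, on a discrete grid of `t_max` time-steps
  (step 0 earliest); stronger drive always fires earlier-or-equally;
* **no error backpropagation** — learning is local (STDP) or locally
  reward-modulated (R-STDP).

These assumptions buy a large computational simplification: a stimulus is
stored as an *accumulative* binary tensor `S[t, f, r, c]` that is 1 from
the neuron's first spike step onward. Convolving every time slice of `S`
with a weight kernel in one pass produces the accumulated membrane
potential of all neurons at all steps; thresholding that potentials
tensor yields the next layer's accumulative spike wave. The redundancy
along the time axis costs a factor `t_max` in memory and is the price of
processing all time-steps simultaneously. The package deliberately does
not offer an event-list representation, leaky dynamics, multi-spike
neurons, or convolution stride above 1.

In R, spike *times* are 0-based values (`0 .. t_max - 1`, `NA` for "never
fires"), while array subscripts are R's native 1-based ones — time-step
`t` lives in slice `t + 1`. Winner coordinates returned by
`get_k_winners()` are 1-based array subscripts.

## The encoder

`input_encoder()` chains three steps:

1. **Filter bank** (`apply_filter_bank()`): cross-correlation (no kernel
   flip, matching deep-learning convention) of the image with a set of
   mean-subtracted kernels, zero-padded so spatial size is preserved.
   Mean subtraction makes uniform regions score zero, which is what makes
   the clip threshold meaningful: responses below `clip_threshold` are
   set to 0 and will never spike. The default bank is six
   difference-of-Gaussians channels (three scales × ON/OFF), the standard
   retina-like front end for this network family.
2. **Local normalization** (`local_normalization()`): division by the
   regional mean (truncated at image borders) plus a floor `eps = 1e-12`
   to keep dark regions from dividing by zero. This flattens global
   contrast so that latency ranks reflect local salience.
3. **Rank-order latency coding** (`intensity_to_latency()`): all strictly
   positive intensities are ranked in descending order and split into
   `t_max` near-equal bins; bin `k` fires at step `k`. Zero intensities
   never spike — binning over the positive support only is the reading
   that preserves "no drive, no spike". When the positive count is not
   divisible by `t_max`, the earliest bins take the extra elements; ties
   across a bin boundary are broken by a fixed row-major scan over
   (feature, row, col), purely for determinism.

`intensity_lateral_inhibition()` is available as an optional sharpening
step. Its scan order is one concrete reading of competitive suppression
among salient points: pixels act in descending order of their *original*
intensity, and a pixel that has already been suppressed loses the right
to suppress its own neighbours. Other readings (iterative recomputation
of the order, energy-based settling) are defensible; this one is chosen
because it is deterministic and single-pass, and it is not part of the
default encoder.

## Layers and competition

* `conv_forward()` is valid-mode, stride-1 spiking convolution. Output
  spatial size is `(H − K_h + 1) × (W − K_w + 1)`; padding is an explicit
  separate operator (`pad_wave()`) whose border neurons never spike. The
  implementation is an im2col matrix product per time slice; the test
  suite pins it to a brute-force per-step oracle exactly.
* `fire()` uses a *strict* crossing (`potential > threshold`). The
  complementary keep-rule of `threshold_op()` (entries `< threshold`
  become 0) means a potential exactly at threshold is kept as
  "reached" by the winner machinery; the measure-zero boundary case is
  documented rather than legislated.
* `pool()` implements max-pooling with output size
  `floor((H + 2·D_h)/R_h) × floor((W + 2·D_w)/R_w)`. This size rule does
  not subtract the window extent before dividing, so with non-divisible
  sizes a window anchored near the border would overrun; such windows
  are truncated at the border, which keeps the printed size always
  realizable. On accumulative binary waves the window maximum *is* the
  earliest spike in the window, so spike-wave in gives valid spike-wave
  out.
* `fire_infinite()` is the decision-layer variant: with an infinite
  threshold nothing ever crosses, so every neuron with non-zero potential
  at the final step fires there. Both the pure wave and the "in-place"
  reading (potentials with all pre-final steps zeroed) are returned,
  since downstream consumers need one or the other.
* `get_k_winners()` selects winners by earliest firing step, then largest
  final potential, then lowest (feature, row, col) lexicographically —
  the last tie-break exists only to make selection fully deterministic.
  After each winner, its whole feature map is suppressed along with a
  Chebyshev square of radius `inhibition_radius` across all maps. The
  full-map suppression is the stronger reading of winner diversity
  ("successive winners learn distinct features") and can be relaxed to
  spatial-only suppression via `suppress_feature = FALSE`.

## Plasticity

`stdp_step()` applies the two-branch rule to each winner's receptive
field (valid-convolution geometry, all input channels). Simultaneous
pre/post spikes (`T_j = T_i`) potentiate; a silent pre-synaptic neuron
(`T_j = NA`) counts as later than everything and depresses. With the
stabilizer on, `ΔW` carries the factor `(W − LB)(UB − W)`, so the bounds
are fixed points and weights started inside them can never escape; with
it off, the bare rate is added and the result clamped. R-STDP is a pair
of rules with negated signs (`reward()` / `punish()`); magnitudes may
differ, and the preset uses a deliberately small positive anti-STDP
`a_minus` so punishment mostly removes drive rather than recruiting
silent synapses. Learning rates are plain scalars — no adaptive
schedules, eligibility traces or delayed reward. One plasticity call is
made per stimulus; silent stimuli trigger none.

## The preset network and its parameters

`tutorial_network()` builds the S1→C1→S2→C2→S3→(global C3) topology.
Parameter choices, with provenance:

| parameter | default | why |
|---|---|---|
| DoG channels | 6 (3 scales × ON/OFF) | standard front end for this family |
| time-steps `t_max` | 15 | typical latency-code resolution |
| S1/S2 kernel, S3 kernel | 5×5, 3×3, 5×5 | the three-stage tutorial geometry |
| S1/S2 winners k, radius | 5 / r=3, 8 / r=1 | feature-learning WTA scale |
| STDP rates | A⁺ = 0.004, A⁻ = −0.003 | slow potentiation-dominant learning |
| S3 weight range | [0.2, 0.8], stabilizer off | bounded reinforcement layer |
| S3 anti-STDP | (−0.004, +0.0005) | weak recruitment on punishment |
| weight init (S1/S2) | N(0.8, 0.05) | early unselective firing |
| weight init (S3) | N(0.5, 0.05) | centred in [0.2, 0.8] so reward and punishment can both act |
| unsupervised epochs | 2 (S1), 4 (S2) | layer-wise schedule |
| conv padding | ⌊kernel/2⌋ | no information loss at borders |

The S3 initialization is centred inside its bounds on purpose: weights
initialized at a bound leave the reward branch nowhere to go under
clamping, and reinforcement then degenerates into pure punishment.

The encoder's `clip_threshold = 0.1` (for images in [0, 1]) is the
operating point at which additive noise of the generator's default level
produces essentially no filter response while bar edges respond strongly.
This matters structurally: if background noise spikes, every decision
neuron's *final-step* potential saturates toward its total weight mass
and decisions become input-independent. Sparse, structure-locked input
spikes are what keep the final-step potential informative.

## The synthetic data generator

`generate_synthetic_dataset()` emulates the statistics this network
family needs from its visual world at desk scale: each class is a
distinct oriented soft-edged bar through the image centre (class k at
orientation kπ/n), with ±1-pixel jitter and additive Gaussian noise
(default sd 0.05), on 24×24 images sized so the three padded kernel
stages produce spikes everywhere. Classes are interleaved in presentation
order. What it does **not** emulate: stroke curvature and thickness
variation, multi-part shapes, occlusion, scale changes, or the intra-class
diversity of handwritten digits. A passing end-to-end test therefore
shows that the machinery — encoding, competition, plasticity, decision —
works and can separate orientation classes; it says nothing quantitative
about performance on natural or handwritten image sets.

## Numerical and degenerate-input choices

* `NA_integer_` is the no-spike sentinel in time grids; it serializes as
  `NA` in the text format, distinguishably from any finite step. Inside
  waves, the all-zero column *is* the encoding of silence.
* The text tensor format writes reals as `%.17g`, newline-terminated,
  no trailing comma, so round trips are bit-exact.
* Degenerate inputs fail loudly: finite spike times ≥ `t_max`, even
  filter windows, inhibition factors outside [0, 1], kernels larger than
  their input, out-of-range feature indices and malformed tensor files
  all raise errors with diagnoses rather than being coerced.
* All stochastic entry points (`conv_layer()` via the caller's seed,
  `tutorial_network()`, `generate_synthetic_dataset()`,
  `selectivity_experiment()`, `run_experiment()`) derive from one
  run-level seed and restore the caller's RNG state, so full pipelines
  are bit-reproducible.

## Problem sizes

The shipped experiments are sized for a single CPU core: the end-to-end
task uses 2 classes × 30 images (2 + 4 unsupervised epochs, up to 20
R-STDP epochs with early stopping at 90 % training accuracy; typical
runs stop after 1–2), and the selectivity experiment shows 400 stimuli
to a 4-feature layer over a 5×5 window, averaged over five seeds. These
sizes are the package's chosen desk-scale operating point; all counts
are arguments and scale up directly.

## Known limitations

* No batch processing: the time axis occupies the tensor dimension that
  a mini-batch would use, which is intrinsic to the accumulative design.
* Convolution stride is fixed at 1; pooling stride is free.
* The decision layer reads only final-step potentials; tasks whose
  classes differ purely in spike *timing* with identical final spike
  sets are invisible to it by construction.
* `train_unsupervised()` cannot detect that earlier layers were left
  untrained; the layer-wise protocol is the caller's responsibility.
* Checkpointing (`save_weights()` / `load_weights()`) stores weights
  only — architecture and rule parameters are reconstructed from code.
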