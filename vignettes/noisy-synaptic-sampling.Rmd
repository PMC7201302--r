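---
title: "Noisy synaptic sampling in spiking winner-take-all networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noisy synaptic sampling in spiking winner-take-all networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synsamp)
```

## The model

`synsamp` simulates supervised learning in a spike-based winner-take-all
(WTA) circuit whose synapses evolve by *synaptic sampling*: the synaptic
parameters $\theta_{ki}$ are treated as samples from a posterior
distribution and follow the stochastic differential equation

$$
d\theta_{ki} \;=\; b\left(\frac{1}{\sigma^2}(\mu - \theta_{ki})
 \;+\; \sum_{n=1}^{N} w_{ki}\,\bigl(x^n_i - \alpha e^{w_{ki}}\bigr)
        \bigl(\Theta\{h^n_k\} - S_k\bigr)\right)dt \;+\; b\,dW_{ki},
$$

with weights $w_{ki} = e^{\theta_{ki} - \theta_0}$ always positive.  The
three drift components are

* a **prior pull** $(\mu-\theta)/\sigma^2$ from a Gaussian structural
  prior over $\theta$;
* an **STDP-like likelihood drift**: $(x_i - \alpha e^{w})$ is a
  simplified plasticity window — potentiating while the presynaptic EPSP
  trace exceeds the weight-dependent threshold $\alpha e^{w}$, depressing
  beyond it — gated by the supervision error $\Theta\{h_k\} - S_k$
  between the one-hot label and the neuron's share of output spikes;
* a **weight-dependent noise term** $dW$ with scale $N\alpha e^{w}$:
  strong synapses (large spines) fluctuate more.  This structured noise,
  rather than constant-scale Brownian noise, is the package's central
  object of study: it concentrates exploration on the large-weight region
  of parameter space where the learning objective has its problematic
  stationary structure.

A run presents stimuli sequentially, one 200-ms window each.  Input
neurons encode a stimulus through Gaussian tuning curves into Poisson
spike trains (5 Hz background), spikes are filtered into EPSP traces
$x_i(t)$ by a double-exponential kernel, output neurons integrate
$u_k(t)=\sum_i w_{ki}x_i(t)$, fire with softmax-normalised rates under a
shared budget (lateral inhibition), and the neuron with the most spikes
names the class.

## Why noise should matter: strict saddles

The trace of the Hessian of the learning objective decomposes into

$$
\sum\lambda\bigl(\nabla^2 f(\theta)\bigr) = A + B + C, \qquad
A = -\frac{KI}{\sigma^2},\quad
B = \sum_{ki}\frac{\theta_{ki}-\mu}{\sigma^2},\quad
C = \sum_{n,k,i} w_{ki}\,\alpha e^{w_{ki}}\bigl(S_k - \Theta\{h^n_k\}\bigr).
$$

$A$ is a negative constant.  $C$ is large and positive exactly when the
network *misclassifies with large weights*: the factor
$w\,\alpha e^{w}$ is tiny for small weights and explosive for large
ones, and $(S_k - \Theta\{h_k\})$ selects neurons that fire in place of
the desired one.  When $A+B+C>0$ the Hessian has at least one strictly
positive eigenvalue — the configuration is a certified *strict saddle*
with a guaranteed descent direction, which stochastic gradient dynamics
can exploit but deterministic dynamics may fail to find.
`hessian_trace_terms()` computes the decomposition,
`count_certified()` counts certificates over (snapshot, input) pairs,
and `reduction_rate()` compares the two training conditions.

## The synthetic sensory environment

All core experiments are download-free.  Each class is a Gaussian
cluster of 3-D points: means drawn per coordinate from
$\mathcal N(0.5,\,0.2)$ and covariance $0.04 I + 0.01\xi$ with
standard-normal $\xi$, symmetrised and eigenvalue-clipped to the nearest
valid covariance.  Two generator choices deserve note:

* **The mean spread 0.2 is read as a variance** (standard
  $\mathcal N(\mu,\sigma^2)$ notation).  We checked both readings with a
  quadratic-discriminant oracle using the true generating Gaussians: under
  the standard-deviation reading the ten clusters overlap so heavily that
  the *Bayes-optimal* accuracy is only ~40–55%, which no classifier can
  exceed; under the variance reading the Bayes bound is ~66–89%,
  consistent with the accuracies this family of networks is known to
  reach.  A `spread_is_sd` flag switches the interpretation.
* Features are **not clipped** to $[0,1]$; the encoder covers the actual
  stimulus range instead (below).

## Parameters, defaults, and why

| parameter | default | meaning / rationale |
|---|---|---|
| $N$ | 1000 | sample-count constant in likelihood and noise scale |
| $\alpha$ | $e^{-6}$ | rate scale of the spike-count likelihood |
| $b$ | $10^{-4}$ | learning rate |
| $\mu,\sigma$ | 0, 1 | prior over $\theta$; initial $\theta$ drawn from it |
| $\theta_0$ | 3 | weight offset; initial weights $\approx e^{-3}$ |
| $T$, $dt$ | 200 ms, 1 ms | presentation window and bin width |
| $R_{\mathrm{total}}$ | 100 Hz | WTA rate budget (~20 output spikes/window) |
| $r_{\max}, r_{bg}$ | 80 Hz, 5 Hz | tuning peak and background rates |
| $\sigma_{tc}$ | 0.35 | tuning width ≈ 0.7 stimulus standard deviations |
| centres | $U(-0.5, 1.5)$ | cover the central ~95% of stimulus mass |
| kernel | $\tau_r=1,\ \tau_d=10$ ms, peak 1 | double-exponential EPSP |
| clip | $\theta \in [-10, 8]$ | keeps $e^{e^{\theta-\theta_0}}$ finite |

The encoder geometry (centres, width) was calibrated once against two
facts: single-trial firing rates should spread nearly uniformly over the
coding range, and the population code must actually support the task — a
multinomial-logit readout of the 1,000-neuron encoding attains ~82% test
accuracy, so the information is present at full scale; with 200 neurons
the same readout caps at ~63–73%, which bounds what any reduced-scale
run can reach.

**Noise scale reading.**  The scale $N\alpha e^{w}$ appears once as a
standard deviation (in prose) and once as the variance of the
Poisson-sum normal approximation whose moments are mean = variance
$= N\alpha e^{w}$ (`poisson_sum_moments()`).  We default to the
**variance** reading.  The practical difference is large: as a standard
deviation the per-update kicks at the learned-weight ceiling
($w \approx 6$) reach $\pm 2$ in $\theta$ and destroy trained structure
in either arm; as a variance they are $\pm 0.02$–$0.05$, which explores
without destroying.  `noise_param_is_std` flips the reading.

**Integration.**  One Euler step per presentation:
$\theta \leftarrow \theta + b\,\Delta t\,(\text{prior} + N\cdot\text{STDP}
+ \xi)$, with $\theta$ clipped to $[-10, 8]$ afterwards.  The reduced
profile uses $\Delta t = 4.8$ so that 3,000 presentations integrate the
same learning time as the full 14,400-presentation schedule (14.4 for
the three-layer schedule of 43,200).  A Wiener-scaled noise option
($b\sqrt{\Delta t}\,\xi$) exists for comparison.

**Test-phase estimate.**  Because the parameters are posterior samples,
a run's test accuracy is the mean over its last three stored parameter
snapshots (`posterior_test_accuracy()`), not the single final draw.  In
saturating runs adjacent snapshots can differ by ±20 accuracy points, so
the final draw alone is an arbitrary lottery; the tail average is the
natural posterior-predictive estimate.

## What the reduced-scale experiments show

`run_comparison()` trains matched-seed pairs (noise on / off) on freshly
generated environments.  The mechanism that separates the arms at this
scale is weight saturation: without noise, trajectories that reach the
large-weight region where $\alpha e^{w} > \bar x$ can lock into
misclassifying high-weight configurations (exactly the configurations
the strict-saddle certificate flags — large $C$), while the
weight-dependent noise keeps those synapses fluctuating and the network
functional.  Accordingly the certified-saddle count of noiseless
snapshots exceeds that of noise-trained snapshots
(`run_saddle_pipeline()`), and mean accuracy with noise exceeds the
noiseless mean.  The size of the accuracy gap varies considerably
between environment draws (some cluster configurations never drive the
noiseless arm into saturation within the schedule); with only three
seed pairs the gap estimate is correspondingly coarse.

## The three-layer extension

`train_deep()` adds a hidden spiking layer organised as parallel WTA
groups of five neurons (each group with its own 200 Hz budget), and the
output-layer rule applies unchanged with hidden traces as inputs
(`output_layer_update()`).  The hidden layer can learn through a
back-propagation rule that distributes the output increments of the
fired and desired neurons onto the first layer
(`hidden_layer_update()`, scale $\beta/\alpha$).  At the reduced sizes
used here every $\beta>0$ we tested (including $\beta=\alpha$ and
$\beta=\alpha/10$, with and without a first-layer prior term) drives the
first layer into saturation — the rule's rank-one updates have no
weight-dependent self-limitation — after which the hidden code is
stimulus-independent and the output layer receives zero expected
likelihood drift.  The shipped default is therefore $\beta=0$: a fixed
random spiking projection.  The consequence is honest but unflattering:
reduced-scale three-layer accuracy does **not** exceed the two-layer
accuracy; the mechanism is implemented and unit-tested, but its benefit
is not reproduced at desk scale.

## Degenerate inputs and numerical choices

* Softmax rates are computed with per-bin max subtraction (shift
  invariant; no overflow).
* An all-silent output window yields all-zero spike shares and predicted
  label 0 (ties break to the lowest index, documented in
  `predict_label()`).
* A non-finite parameter update raises an error naming the synapse.
* `reduction_rate()` requires $S_2>0$; the pipeline reports an undefined
  rate when nothing certifies.
* Per-sample evaluation seeds derive from `sample_id`, so accuracy is
  invariant to row order.

## What passing tests do and do not show

The generator emulates the study conditions (cluster geometry, tuning
encoders, Poisson spiking, matched-seed pairing) but not features of
real sensory data: no temporal structure within a presentation beyond
rate coding, no refractoriness, no input correlations, no
train/test distribution shift.  Reduced problem sizes (200 input
neurons, 3,000 presentations, 3 seed pairs, hidden size 100) keep the
whole suite within desk budgets; they also cap attainable accuracy well
below full-scale values and make the noise-benefit estimate coarse, as
discussed above.  Full-scale settings are available via
`synthesis_profile("full")`.
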