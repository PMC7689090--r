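---
title: "Training spiking networks with global feedback targets and local STDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training spiking networks with global feedback targets and local STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifnet)
```

## The problem

Backpropagation trains deep networks by sending exact error gradients
backwards through the transposes of the forward weights. Biological
circuits have no mechanism for such weight transport, and spiking neurons
have no usable derivative at the spike. `lifnet` implements a training
scheme that avoids both obstacles: a multi-layer network of
conductance-based leaky integrate-and-fire (LIF) neurons is trained by
(1) projecting the output error to each hidden layer through *fixed random
feedback matrices*, which turns the error into per-layer *activity
targets*, and (2) updating each forward weight matrix with a purely *local*
differential STDP rule — presynaptic activity times the postsynaptic gap
between forward state and target. No gradients travel backwards, no
feedback weights are learned, and every layer updates simultaneously.

## Neuron model

Each neuron integrates a membrane potential $V$ with leak conductance
$g_L$ toward the leak potential $V_L$, driven by an excitatory conductance
$g_E$ toward the reversal potential $V_E$:

$$\tau_m \frac{dV}{dt} = -(V - V_L) - \frac{g_E}{g_L}(V - V_E), \qquad
  \tau_E \frac{dg_E}{dt} = -g_E + \textstyle\sum_j w_{j,i} S_j.$$

The discrete update (step $dt$) applies the membrane equation with the
conductance from before the step, then relaxes the conductance toward the
weighted presynaptic input, then thresholds: a neuron with $V > V_{th}$
(strict) emits $\delta = 1$ and resets to $V_{reset}$. The layer's output
is the residual-style surrogate

$$S_i = \textstyle\sum_j w_{j,i} S_j + \tau\,\delta_i,$$

i.e. the weighted input carried through unchanged plus a small spike
bonus $\tau$. This real-valued signal is what crosses layers and what the
learning rule reads; it is why a 10-step simulation suffices to drive deep
layers. The update order (membrane from pre-step conductance, conductance,
threshold, surrogate) is fixed as the package's single canonical
semantics; scalar-loop oracles in the test suite pin it bit-for-bit.

There is no inhibitory channel, no refractory period, and no adaptive
threshold. An inhibitory reversal potential would enter the voltage
equation exactly as the excitatory one does, but no term in the model uses
it, so none is implemented.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `V_L`, `V_reset` | 0 | leak potential; post-spike reset |
| `V_E` | 0.2 | excitatory reversal potential |
| `V_th` | 0.0009 | firing threshold (strict) |
| `tau_m`, `tau_E` | 0.5, 0.2 | membrane / conductance time constants |
| `g_L` | 20 | leak conductance |
| `tau_s` | 0.01 | surrogate spike amplitude |
| `dt`, `T` | 0.01, 0.1 | step and total simulated time (10 steps) |

Potentials share one arbitrary-unit scale and the time constants one time
unit. `dt/tau_m` and `dt/tau_E` must not exceed 1 or the explicit update
diverges; the constructor enforces this, along with `V_reset <= V_th`
and an integer step count.

With the threshold out of reach and constant drive $d$, the dynamics have
closed forms the tests verify to $10^{-10}$ or better: $g_E \to d$
geometrically with factor $(1 - dt/\tau_E)$ per step, and
$V \to (g_L V_L + d\,V_E)/(g_L + d)$ — e.g. $V^* = 0.1$ at the defaults
with $d = 20$.

## Forward simulation

Inputs are vectors in $[0,1]$ used *directly* as the input layer's
surrogate output at every step — a constant-current-style encoding.
Stochastic (Poisson) spike coding is deliberately not used: the surrogate
is real-valued by construction, so nothing requires a rate code, and the
deterministic encoding keeps every run bit-reproducible. Within each
global step, layers advance once in ascending order, each consuming the
surrogate its predecessor just produced; the loss and the learning rule
read only the final step's surrogates. The number of weight layers may
not exceed `T/dt` (10 at the defaults), which guarantees each layer at
least one settled, input-driven step; deeper networks are rejected rather
than silently under-simulated.

## Targets and the local update

For a batch, the output target $S^T$ is the one-hot label row (amplitude
1.0 — the amplitude is a documented package default, exposed as an
argument). The signed per-sample error is the gradient of the summed
squared loss, $e = 2(S_{out} - S^T)$. Targets:

* **penultimate layer**: $\hat S = S - \eta_t\, e\, W_{top}^\top$ — the top
  weights themselves pull the error back (no feedback matrix needed);
* **deeper hidden layers**: $\hat S_l = S_l - (B_l e + b_l)$ with $B_l$
  drawn once, entries $\mathcal N(0, (1/\sqrt{n_l})^2)$, then frozen.

The feedback entries are normalized by the *receiving* layer's width
$n_l$, which makes the projected shift $B_l e$ norm-preserving in $e$.
Normalizing by the error dimension instead inflates the projection's
leading singular value by roughly $\sqrt{n_l/n_{out}}$; for few classes
this puts the update loop's gain above 1 and we observed immediate,
violent divergence (loss overflowing within an epoch) in a seed-dependent
fraction of deep runs, whereas the receiving-width normalization was
stable across every seed probed.

The weight update is local: $\Delta W = S_{pre}^\top (S_{post} - \hat
S_{post})$, averaged over the minibatch (the mean keeps $\eta_w$
meaningful across batch sizes; a sum reduction is available), applied as
plain SGD $W \leftarrow W - \eta_w \Delta W$ with $\eta_t = 0.5$,
$\eta_w = 0.015$, batch size 10 as the standard recipe. All weight
matrices update from the same frozen forward trace; nothing is
re-simulated between layer updates.

**The feedback bias defaults to zero.** A frozen nonzero $b_l$ makes the
target differ from the forward state even at zero error, so weights drift
unconditionally; at depth this drift compounds and we observed it drive
otherwise-converged 5-layer runs into numerical divergence, while the
zero-bias variant was stable across every feedback scale we probed. Zero
bias is also what makes "zero error implies no update" an exact fixed
point of the whole cascade. A `bias_scale` argument re-enables it.

## Ablating feedback layers

`n_feedback_layers` grants direct-feedback targets to the deepest `k`
eligible hidden layers (those below the penultimate one), shallower
layers last. Layers without a target freeze their incoming weights
bit-exactly. At `k = 0` every random projection is removed, yet the top
*two* weight matrices still learn: the output weights (one-hot target)
and the penultimate layer's incoming weights, whose target needs only the
forward-weight transpose. The eligible count for an $L$-layer network is
therefore $L - 3$.

## Synthetic data

`make_blobs()` generates the package's test bed: class centers on a
sphere of radius `separation * noise_sd` (rejection-sampled until all
pairwise center distances reach that radius), isotropic Gaussian samples
around them, a fixed shift-and-clip map into $[0,1]$, and a deterministic
2:1 train/test split per class. The standard conditions used throughout
the tests are 20 dimensions, 3 classes, separation 6, noise 0.05, and 300
samples per class (600 train / 300 test). This preserves what the learner
consumes from image data — bounded inputs with class-conditional cluster
structure — but none of the pixel correlations, manifold structure or
class overlap of real images, so passing results demonstrate the
correctness and stability of the learning machinery, not image-benchmark
performance. Real IDX image files flow through the identical pipeline via
`read_idx_images()`. One caution for image-shaped synthetic data: input
statistics matter for stability. The top-layer update multiplies the
output error by roughly $\eta_w \lVert S_{pen}\rVert^2$ per batch, and
activity norms track the input norm, so dense inputs with every pixel
near 0.5 ($\lVert x\rVert^2 \approx 196$ at 784 dimensions) push that
factor past the oscillatory-divergence boundary, while sparse "ink"
statistics like real digit images ($\lVert x\rVert^2 \approx 100$) stay
inside it. The test suite's image-shaped check therefore generates
sparse per-class pixel templates rather than dense blobs.

With nearly non-overlapping clusters (half the inter-center distance is
about $3\sigma$), a nearest-centroid classifier already exceeds 99%; the
network is expected to reach at least 95% under the standard recipe, and
the value of the test lies in the full pipeline achieving it through
spiking dynamics, random feedback and local plasticity.

## Problem sizes and numerical choices

The shipped tests train [20-64-64-3] networks for 100 epochs (seconds per
run) and run the ablation staircase on [20-32-32-32-32-3] for 15 epochs
over several seeds; the image-shaped pipeline check uses a
[784-256-256-10] network for 10 epochs on 900 synthetic samples. These
sizes were chosen so the whole suite completes on a laptop-class single
core in minutes while still exercising depth, ablation and the IDX path.

Everything is double precision — the threshold (9e-4) sits too close to
single-precision accumulation noise for anything less. All randomness
(weight draws, feedback draws, per-epoch shuffles, blob sampling) derives
from user-provided integer seeds through fixed streams, so any result in
this package reproduces bit-exactly from its configuration; argmax ties
in evaluation break to the lowest class index by rule.

## Known limitations

* Fully connected layers only; no convolutional or recurrent structure.
* No inhibition, refractoriness or threshold adaptation.
* The constant-input encoding makes the surrogate pathway nearly linear
  in the input; tasks requiring strongly nonlinear features will learn
  more slowly than the spiking nonlinearity alone might suggest.
* Fixed epoch budgets, plain SGD; no early stopping, momentum or
  regularization — deliberately, to keep the learning rule bare.
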