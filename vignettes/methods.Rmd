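---
title: "Learning without synaptic plasticity in recurrent spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning without synaptic plasticity in recurrent spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnn)
```

## The scientific question

Synaptic plasticity is slow: experimentally grounded learning rules need many
repetitions of a trial, yet animals routinely learn from a single one. One
candidate resolution is a two-tiered scheme — *learning-to-learn* (L2L): slow
processes (evolution, development, prior learning) tune the synaptic weights
of a recurrent circuit so that, with those weights **frozen**, the circuit's
own dynamics can absorb a new task instance within one episode. This package
implements that scheme for recurrent spiking neural networks (RSNNs) of leaky
integrate-and-fire (LIF) neurons, a fraction of which carry spike-frequency
adaptation (SFA). The slowly decaying adaptive thresholds of the SFA neurons
are the network's hidden memory substrate on the seconds time scale; the
outer loop trains all synaptic weights by surrogate-gradient backpropagation
through time (BPTT) across a family of tasks, and the inner loop is pure
simulation with fixed weights.

## The neuron model

In discrete time (step $\delta t$ = 1 ms), each neuron $j$ evolves as

$$V_j(t+\delta t) = \alpha V_j(t) + (1-\alpha)\,R_m I_j(t) - v_{\mathrm{th}} z_j(t),
\qquad \alpha = e^{-\delta t/\tau_m},$$

with input current
$I_j(t) = \sum_i W^{\mathrm{in}}_{ji} x_i(t-d^{\mathrm{in}}_{ji})
        + \sum_i W^{\mathrm{rec}}_{ji} z_i(t-d^{\mathrm{rec}}_{ji})$
summing delayed input spikes $x_i$ and recurrent spikes $z_i$
(delays $\ge$ 1 ms: no same-step recurrence). A spike is emitted when the
membrane potential strictly exceeds the threshold; the reset is subtractive.
SFA neurons replace the fixed threshold $v_{\mathrm{th}}$ by

$$A_j(t) = v_{\mathrm{th}} + \beta\, a_j(t), \qquad
a_j(t+\delta t) = \rho_j a_j(t) + (1-\rho_j) z_j(t), \qquad
\rho_j = e^{-\delta t/\tau_{a,j}},$$

so each spike raises the threshold, which decays back with time constant
$\tau_a$ (hundreds of ms to seconds). $\beta = 0$ recovers the plain LIF
neuron bit-exactly, which the test suite asserts.

Three modelling choices that the model description leaves open, and how this
package resolves them:

* **Reset magnitude for SFA neurons.** The reset always subtracts the fixed
  baseline $v_{\mathrm{th}}$, not the current adaptive threshold $A_j(t)$ —
  the membrane recursion is used literally, and the adaptive part of the
  threshold only gates spiking.
* **Within-step order.** The spike decision is taken on the *pre-update*
  potential: $z(t) = H(V(t) - A(t))$, then $V, a$ advance using $z(t)$. This
  is the order that makes the published membrane recursion self-consistent.
* **Refractoriness.** After a spike the neuron cannot fire for
  $\lceil \tau_{\mathrm{ref}}/\delta t\rceil$ steps, but the membrane keeps
  integrating through the refractory period (only the spike is gated; the
  potential is not clamped).

Voltages are carried in mV. The weight scale is $w_0$ = 1 Volt (1000 mV):
initial weights are $\mathcal N(0, w_0^2/n_{\mathrm{in}})$, which gives a
spiking (but sparse) network at initialisation, and the optimizer treats
$W/w_0$ as the trainable quantity (see *Outer loop* below).

## Surrogate gradients

The spike Heaviside has no derivative, so BPTT uses the dampened
pseudo-derivative

$$\frac{dz_j(t)}{dv_j(t)} := \gamma \max\{0,\, 1 - |v_j(t)|\},
\qquad v_j(t) = \frac{V_j(t)-A_j(t)}{A_j(t)},$$

with $\gamma = 0.3$. The adaptation recursion is linear in $a$ and is
differentiated exactly (no dampening); the refractory gate is treated as a
non-differentiable constant, so the pseudo-derivative is zeroed while the
neuron is refractory; the reset term reuses the same spike node, so its
gradient flows through the same pseudo-derivative. The backward pass
(`rsnn_backward`) is hand-written reverse mode over the recorded forward
trajectory; the test suite verifies it in two independent ways:

1. against central finite differences in a regime where the network is
   provably smooth (inhibition keeps $V \le 0$, where the surrogate is
   exactly zero and the model is a linear filter), and
2. against a forward-mode tangent propagation through the *identical*
   surrogate graph, written separately in the test helpers, in the spiking
   regime — the two agree to better than $10^{-6}$ relative (in practice to
   machine precision).

## Network construction, Dale's law, and rewiring

Unconstrained networks use dense Gaussian initialisation as above. For the
navigation task the network obeys Dale's law: each neuron has a sign
$\kappa_i$, all its outgoing recurrent and readout weights share that sign,
and weights are initialised column-wise as $\kappa_i\,|\mathcal N(0,1)|$.
Rows are then balanced so excitatory and inhibitory input cancel, and the
matrix is normalised by its largest eigenvalue modulus. One deliberate
deviation: the balancing is a sign-preserving *rescaling of the inhibitory
group* per row rather than a literal additive constant — an additive
constant flips the sign of small-magnitude entries and would violate the
very sign constraint the initialisation exists to enforce. Row sums are
exactly zero either way.

Sparse networks are trained under rewiring with a fixed global budget: a
connection whose update would flip it against its sign is disconnected and a
new coordinate (drawn uniformly from the inactive pool spanning input,
recurrent and readout matrices) is activated at weight zero with its stored
sign. The active-connection count is conserved exactly, verified across
$10^3$ random steps in the tests. The rewiring noise temperature is 0, so
the only stochastic element is the reconnection draw. L1 shrinkage (0.01,
in units of each matrix's weight scale, times the current learning rate) is
applied to active weights.

## Task families

All data are generated programmatically; there are no external inputs.

* **Sinusoid meta-regression.** Targets $y = A\sin(\phi + x)$ on
  $x \in [-5,5]$, $A \sim U[0.1,5]$, $\phi \sim U[0,\pi]$. An episode is
  K = 500 steps of 20 ms; each step presents a fresh $x^k$ plus the
  *previous* step's target $y^{k-1}$ as feedback (0 at the first step).
  Inputs are encoded by 100-neuron Gaussian population codes (peak 200 Hz);
  the readout is affine on the per-step mean firing rates (spike
  count / 20). Loss: summed squared error per episode plus
  $\lambda (f_{\mathrm{avg}} - f_0)^2$ with $\lambda = 30$, $f_0 = 20$ Hz.
  The tuning width of this task's codes is a package decision: the source
  description's cross-reference for the sinusoid encoding resolves to no
  encoding section, and transplanting the arm task's width (range/1000,
  i.e. a tenth of the centre spacing) makes the code nearly silent —
  roughly one input spike per 20 ms presentation against tens of background
  spikes, which starves the episode of information about $x$. The package
  uses width = range/100 ($\sigma$ = 0.1, about one centre spacing), the
  standard population-code geometry and the same width-to-spacing
  proportionality as the maze place-cell code. The arm task keeps its
  explicitly printed range/1000.
* **Two-link arm forward model.** Arms with masses and lengths
  $\sim U[0.5,2]$ are driven by torques refreshed every 10 ms; the network
  sees the torques and the joint angles delayed by 100 ms (silent for the
  first 100 ms) and predicts the current angles from an exponential-trace
  readout ($\tau$ = 50 ms). The plant is the canonical planar double
  pendulum with point masses at the link ends, gravity 9.81 m/s², no
  friction, integrated by RK4 at 1 ms; the equations of motion are a
  modelling choice (the original description defers to prior work), as is
  the torque law $U[-5,5]$ N·m per 10 ms block and the $[-2\pi, 2\pi]$
  encoding range for angle feedback. Energy conservation under zero torque
  is a test oracle.
* **Water maze.** A circular arena of radius 1; goal disks of radius 0.3
  centred uniformly on the 0.85 circle; 2000 steps per episode. Positions
  are place-cell coded (40 neurons per coordinate, rate
  $500\,e^{-100(\xi_i-\xi)^2}$ Hz); rewards arrive as synchronous spike
  volleys in two 40-neuron groups (+1 on goal, −0.02 on wall). Five
  non-spiking leaky-integrator readouts ($\tau$ = 20 ms) give the Gaussian
  policy (means via tanh, variances via sigmoid) and the value estimate;
  actions scale to velocities of norm at most 0.02, wall crossings are
  projected back to the border. Wall and goal can pay out in the same step;
  the rewards add. Training uses the clipped-surrogate policy objective
  (clip 0.2, discount 0.99, finite-horizon returns without bootstrapping, no
  generalised advantage estimation, one optimizer step per batch of K = 10
  episodes) plus value, entropy and firing regularisers; trajectories are
  conditioned on recorded per-step current noise whose per-neuron scale
  $\nu_j$ (init 0.03) is trained alongside the weights.
* **One-shot pattern store / complete / delete.** Three random 25-bit
  patterns (Bernoulli(0.5) per bit) are shown once (phase A), then partial
  cues (each 1-bit dropped with p = 0.4) must be completed to the stored
  patterns (phase B); after a 3-bit deletion cue (phase C) the same partial
  cues must map the deleted index to the *nearest kept pattern by Hamming
  distance* (phase D; ties break to the lower index — a determinism choice).
  Every item and the cue are presented for 100 ms; phase-A items have no
  targets. Bits are coded by 5 neurons each at 200 Hz (bit = 1) or 2 Hz
  (bit = 0); outputs are logistic-squashed trace readouts ($\tau$ = 100 ms),
  with the per-item probability taken as the logistic of the readout's mean
  over the item window. The loss is the standard bitwise binary
  cross-entropy: the sign as printed in the source description
  ("$y\log p - (1-y)\log(1-p)$") is not a proper loss, so the package uses
  the conventional "+" form, plus the firing regulariser with $\lambda = 5$.

## The outer loop

`rsnn_l2l()` samples a batch of task instances per iteration, simulates one
frozen-weight episode per instance, forms the family's loss, and applies one
Adam update to all weights. Input and recurrent weights are optimised in
units of $w_0$ (i.e. Adam steps move $W/w_0$); this is the point of the
$w_0$ convention — it puts the trainable quantities on the unit scale where
Adam's absolute step size (learning rate $10^{-3}$) is meaningful. Readout
weights and biases live in task units and are trained as-is. The maze
schedule starts at learning rate 0.01, halved every 5000 iterations, with
Adam's $\epsilon = 10^{-5}$.

Full-episode BPTT is used (no truncation). Gradients across a batch are
averaged, matching the expectation over tasks in each loss.

## Probing the internal model and the linear baseline

`internal_model_probe()` makes the network's current belief visible: a
stored mid-episode snapshot (potentials, adaptation variables, refractory
counters, delay buffers) is copied, one 20 ms input presentation is
simulated per grid value, and the decoded outputs are returned as a curve —
the original episode can be resumed bit-exactly, which the tests assert. The
probe presents each grid value once for 20 ms over a 101-point grid on
$[-5,5]$ (grid and repetition count are package choices; the source
description does not fix them), with the feedback channel silent.

`linear_baseline()` is the analog-value comparison: per episode, ordinary
least squares (slope + intercept) on the first 250 $(x, y)$ pairs, mean
squared error on the last 250, averaged over $\ge$ 5000 episodes. This
yields $\approx 4.03$; `scripts/acceptance.R` recomputes it from scratch.

## Scales, tolerances, and what the tests do and do not show

Problem sizes in the test suite are desk-scale by design: the published
full-scale configurations (100–600 neurons, 5000–100 000 iterations,
30-second arm episodes) are shipped as `*-paper` presets and validated
structurally, but the suite trains only the `sinusoid-desk` preset — 80
neurons, 100-step episodes, batch 20, 200 iterations, roughly ten minutes on
one CPU. Two settings of the desk preset are deliberate rescalings of the
published schedule rather than copies of it. First, the firing-penalty
coefficient is $\lambda = 6$, not 30: the data term of the loss sums over
the episode's steps, so shortening episodes from 500 to 100 steps shrinks
it fivefold while the penalty does not — $\lambda$ is scaled by the same
factor (30 · 100/500) to preserve the published balance between the data
term and the regulariser. Without this, weight gradients at desk scale are
dominated by penalty fluctuations and the run learns only the firing rate.
Second, the learning rate starts at $10^{-2}$ and halves every 100
iterations, ending at the published $2.5\times10^{-3}$ scale: a run with
25× fewer, 5× smaller batches needs proportionally larger early steps to
traverse the same distance, and the decay restores late-run stability (the
same warm-then-decay pattern the full-scale navigation schedule uses). The
desk run must halve its smoothed training loss and beat the same-protocol
linear baseline on held-out tasks; it is *not* expected to reach the
full-scale endpoint errors (e.g. test MSE 0.1968 for the sinusoid family),
which required cluster-scale training and are retained as full-scale claims
only.

What passing desk-scale tests show: the dynamics are exact (closed-form
oracles), the gradients are exact for the surrogate graph (dual oracles),
the environments honour their contracts, and the full training stack
genuinely learns. What they do not show: quantitative reproduction of
full-scale endpoints, robustness of the arm model to the unknown original
torque law and mass placement, or behaviour on real neural data — the
generators emulate the published synthetic conditions, not biology.

## Numerical choices

* Bernoulli-per-bin spike sampling (p = rate·$\delta t$, capped at 1) keeps
  spike tensors binary; at $\le$ 500 Hz and 1 ms bins it is
  indistinguishable from Poisson sampling.
* Probabilities in the cross-entropy are clipped to $[10^{-12},
  1-10^{-12}]$.
* The wall-intersection root in the maze uses the stable quadratic form and
  renormalises positions that land within rounding error outside the disk.
* Degenerate baseline episodes (constant inputs) are skipped with a warning.
* All stochastic components draw named sub-seeds from the master seed via a
  counter-based mixing scheme (`derive_seed`), so init, data and noise
  streams are independent and every artifact is reproducible bit-for-bit;
  checkpoints store the RNG state and resume exactly.

## Known limitations

* The simulator is clock-driven at 1 ms; sub-millisecond spike timing is
  quantised (the time-rescaling test bounds the discretisation error).
* Hand-written reverse mode covers the shipped readouts and losses; a new
  readout type needs its adjoint.
* The maze loop steps the environment in R per time step, which is the
  slowest path in the package; full-scale navigation training is a cluster
  job, not a desk run.
* Checkpoints serialise to JSON text (17 significant digits — exact for
  doubles); raster export is CSV event lists. No HDF5 container is used.
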