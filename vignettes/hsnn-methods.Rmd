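---
title: "Heterogeneous spiking networks: model, calculus and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous spiking networks: model, calculus and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsnn)
```

## The model

`hsnn` simulates feedforward spiking convolutional networks whose temporal
memory comes from *neuronal heterogeneity* rather than recurrence.  The
building block is a leaky integrate-and-fire (LIF) membrane

$$\frac{dv}{dt} = a + b\,v + c\,I,
\qquad v \leftarrow v_{reset} \;\text{ if } v > v_{threshold},$$

with a refractory period of $r$ ms after each spike.  The mapping to the
classical constants is $b = -1/\tau_m$ and $c = R_m/\tau_m$.  Three
parameterizations with different decay rates coexist in one network:

| type       | $a$ (1/ms) | $b$ (1/ms) | $c$   | $r$ (ms) | role |
|------------|-----------:|-----------:|------:|---------:|------|
| learner    | $-4.1$     | $-0.01$    | 0.31  | 20       | STDP feature learning |
| short-term | $-5.1$     | $-0.02$    | 0.45  | 10       | fast-decaying memory |
| long-term  | $-1.6$     | $-0.001$   | 0.16  | 10       | slow-decaying memory |

Synapses carry bounded conductances $G \in [G_{min}, G_{max}]$ updated by
pair-based STDP with *soft bounds*: potentiation
$\Delta G_p = \alpha_p e^{-\Delta t (G - G_{min})/(\tau_{pot}(G_{max}-G_{min}))}$
and depression
$\Delta G_d = \alpha_d e^{-\Delta t (G_{max} - G)/(\tau_{dep}(G_{max}-G_{min}))}$,
with defaults $\alpha_p = 0.1$, $\alpha_d = 0.03$, $\tau_{pot} = 10$ ms,
$\tau_{dep} = 80$ ms, $G \in [0, 1]$.  The pairing policy is
nearest-neighbor: each post-synaptic spike pairs with the most recent spike
of each afferent.  Because "no recent afferent spike" needs a horizon to be
decidable online, a post spike whose afferent has been silent for the whole
`ltdWindow` (default 50 ms) depresses that synapse at the window edge; this
keeps memory bounded and the update continuous at the boundary.
Acausal pairs (nearest pre spike *after* the post spike) depress with the
absolute lag — the printed signed lag would make the LTD exponent explode.

## The operating point: reset and threshold are calibrated, not assumed

The published parameter set fixes $\{a, b, c, r\}$ per type but *not*
$v_{reset}$ or $v_{threshold}$.  This matters: with the naive choice
$v_{reset}=0, v_{threshold}=1$, the learner membrane relaxes toward
$-a/b = -410$, so rate-coded input at $\le 100$ Hz can never reach
threshold and the convolution stack would be silent.

The cut-off table of the reference parameterization resolves this.  The
exact cut-off frequency of a neuron driven through conductance $G$ is

$$f_0 = \frac{b}{\ln\!\big(X/(X + cG)\big)}, \qquad X = v_{reset} + a/b,$$

so one measured cut-off pins down $X$ (`calibrateOffset()`): the learner
reference cell (105.8 Hz at $G = 0.1$) gives $X = 0.3127$.
`calibratedNeuron()` therefore anchors each preset at
$v_{reset} = X - a/b$ with the threshold a configurable span above reset
(default 1).  This single constant per type simultaneously (i) reproduces
the reference cut-offs, and (ii) puts network neurons in a regime where a
handful of coincident afferent spikes fire them — which is what the
convolution layers need.  `cutoffTable()` reproduces the whole reference
table from the $G=0.1$ column alone via the constant-leak law
$f_0 = s/(cG)$, whose exact $1/G$ scaling matches the table's printed
columns to within one unit of the last printed decimal (the printed table
mixes rounding and truncation, so agreement tighter than $\pm 0.1$ Hz is
not defined).

The sign in the $f_0$ denominator is worth a note: naively transcribing the
source algebra gives $X - cG$, which yields a negative period.  Solving the
zero-gain condition cleanly gives $X + cG$, which is what the package
implements and what simulation confirms.

## The pathway calculus and what "simulation agreement" means

A *memory pathway* is an ordered chain of long/short-term neurons, one per
layer, with uniform refractory $r$ and per-stage spike-accumulation counts
$\gamma_i$ (spikes needed to cross threshold).  Its rate-transfer function
is

$$\Phi(f_{in}) = \Big(r + \frac{\prod_i \gamma_i}{f_{in}}
 + r \sum_{k=0}^{m-2}\prod_{j=0}^{k}\gamma_{m-j}\Big)^{-1},$$

the $m$-fold composition of the single-stage response
$F(f) = f/(\gamma + r f)$.  Ordered $\gamma$ sequences determine $\Phi$, so
differently composed pathways are distinguishable (`responsesDistinct()`),
and inverting the chain at the last stage's cut-off yields the retention
length $T$ (`retentionLength()`).

One subtlety surfaced when cross-validating the calculus against
simulation, and is worth knowing before trusting either number.  The
calculus charges every output cycle the full collection time
$\gamma/f_{in}$ *plus* the full refractory period $r$: it implicitly
assumes that spike collection restarts one full input period after
refractory release.  A *free-running* periodic drive does not cooperate:
the output phase locks to the input grid and the simulated cycle only loses
$\lfloor r/T \rfloor \, T$ of input (with $T = 1/f_{in}$), so the simulated
rate sits *at or above* $\Phi(f_{in})$, with equality exactly when $T$
divides $r$.  For $\gamma = (2,3)$, $r = 10$ ms at 40 Hz the discrepancy
reaches 21%.  `simulatePathway()` therefore offers both conventions:

* `mode = "aligned"` (default): an event-driven simulation of each stage's
  membrane (leak, jumps, threshold, refractory all simulated) whose
  afferent train restarts one period after refractory release — the timing
  model under which the calculus is derived.  Agreement with $\Phi$ is
  within 5% over pathways of length up to 3 and inputs of 20–100 Hz, and
  the residual measures leak-induced inflation of $\gamma$.
* `mode = "free"`: the plain Euler chain.  It matches the calculus at
  commensurate drives (e.g. 100 Hz against $r = 10$ or 20 ms) and
  otherwise runs faster than predicted, never slower — asserted as a test
  property.

Similarly, the closed-form cut-off describes when periodic input can lift
the membrane above reset *at all*; it equals the simulated firing boundary
when the threshold sits one per-spike jump $cG$ above reset, which is the
convention `simulateCutoff()` probes (bisection, within 2 Hz).  With larger
thresholds the simulated boundary is strictly higher.

### Stage gammas and the retention ordering

$\gamma$ per type is not printed.  Two facts pull in opposite directions:
long-term neurons have the lowest cut-off (they respond to the slowest
input) but also the smallest input gain $c$, so at *equal* threshold span
they would need the most spikes per stage — which would make all-long
pathways retain *shortest*, inverting the qualitative claim of the model
(short-term chains = shortest retention, long-term = longest).  Since the
per-stage threshold span is part of the same unprinted operating point as
$v_{reset}$, the package fixes the default stage parameters once
(`pathwayDefaults()`: $\gamma_{long} = 2$, $\gamma_{short} = 3$,
$\gamma_{learner} = 4$, with per-type cut-offs from the calibrated $1/G$
law at unit conductance) so that the qualitative retention ordering of the
model is realized; with these defaults all eight length-3 long/short
pathways have distinct retention lengths ordered all-short < mixed <
all-long.

```{r retention}
Ts <- sapply(list(pathwaySpec(rep("short", 3)),
                  pathwaySpec(c("short", "long", "short")),
                  pathwaySpec(rep("long", 3))), retentionLength)
round(Ts, 2)  # ms, increasing
```

## Network architecture

Each convolution layer holds a plastic **learner module** (all learner
neurons) and a frozen **memory module** with one long-term and one
short-term population sharing the kernels transferred from the learner
(`transferConductance()`, idempotent; memory kernels change through no
other operation).  Both memory populations project to the next layer
(crossover superposition), so every ordered long/short sequence across
layers exists as a pathway; since the populations are replicated copies of
one kernel tensor, parameter counting is per-layer
$k_h k_w d_{in} d_{out}$ — the reference stack
Conv2D{[3x3,32],[3x3,64],[5x5,128],[7x7,40]} on single-channel input has
474,400 trainable conductances (`countParameters()`).

Inhibition is winner-take-all and only ever removes spikes:

* **cross-depth** (learner modules): one winner per spatial location per
  step, by highest pre-update membrane potential, ties to the lowest depth
  index.  In the learner path a winner also resets the membranes of all
  other depths at its location; without this "receptive-field ownership"
  every kernel integrates everywhere and all kernels converge onto the same
  saturated pattern, while with it oriented toy stimuli yield clean
  orientation-selective kernels (see the test suite).
* **local** (all modules): a winner suppresses spiking neighbors within a
  Chebyshev radius (default 1) in its own depth map.
* **section-lateral** (prediction module): a spike suppresses only units of
  its own objective section, keeping objectives independent.

Memory modules skip cross-depth inhibition (they perceive rather than
compete) and scale their thresholds by a per-layer factor
(`thresholdScale`, defaults 1.0/0.8/0.6/0.5 along the reference stack —
declared package defaults for the "tuned hyperparameter" of the source
model) to counteract diminishing spike frequency in depth.

Training is layer-wise and unsupervised: frames are rate-encoded (pixel
intensity $\mapsto$ 0–100 Hz; Poisson draws by default, periodic trains
where the analytic assumptions matter), layer $k$'s learner adapts by STDP
while layers $1..k{-}1$ perceive through frozen memory kernels, then the
learned kernels are transferred and layer $k{+}1$ starts.  Neuron state is
reset between sequences, making features order-independent.  The
multi-objective readout is a single sigmoid layer on the last memory
module's per-neuron spike frequencies, trained by mini-batch SGD on binary
cross-entropy over concatenated one-hot blocks (one per objective) — a
deliberately dependency-light implementation of a linear readout.

## Synthetic data

`makeDataset()` renders procedurally generated sprites (bars, crosses,
blobs, rings — no external imagery) on a dark canvas under the five motion
dynamics (static, constant, accelerating, decelerating, oscillating) for
translation and rotation independently.  Defaults: 32×32 canvas, 10
frames, translation speed 2 px/frame, acceleration speed/5 per frame,
oscillation amplitude 4 px with period 8 frames, rotation 15°/frame
equivalents; oscillation is sinusoidal and deceleration clamps the speed at
zero.  Training sequences use the exact base parameters; test sequences
redraw each dynamic parameter from a Gaussian centered on the training
value with standard deviation `sigmaTs` (default 1), so test sequences are
near but never identical to training conditions.  Rendering uses an
inverse-mapped bilinear resampler for sub-pixel translation and rotation;
trajectories are auto-centered and clamped (or rejected) at the canvas
edge.

What the generator deliberately does *not* emulate: sensor noise, cluttered
backgrounds, multiple simultaneous objects, occlusion, and event-camera
timing statistics (event streams are supported as input via
`eventsToFrames()`, but the generator produces clean frames).  Passing the
toy-task tests therefore demonstrates that the pipeline's mechanics work
end to end — encoding, STDP, transfer, rate features, multi-objective
readout — not that the architecture reaches any particular accuracy on
real footage.

## Numerical choices

* Integration is forward Euler on a 1 ms grid (the unit timestep of the
  study conditions); `dt` is configurable and fine grids serve as oracle
  checks.  Euler tracks the closed-form membrane to $10^{-3}$ at
  $dt = 10^{-2}$ ms for order-1 potentials; the presets roam $O(100)$
  potentials where the same bound needs $dt = 10^{-3}$ ms (error is
  first-order in $dt$; both are asserted in the tests).
* Spike condition is strict ($v > v_{threshold}$) after the update; during
  refractoriness the membrane is clamped at $v_{reset}$ and input is
  discarded; the refractory window blocks exactly $r$ ms.
* Time bins are half-open $[t, t+1)$ ms; coordinates are 0-based row-major
  in file formats, 1-based inside R.
* Response-function inversion is monotone bisection to $10^{-9}$ spikes/ms.
* Winner selection everywhere is deterministic (potential, then lowest
  index), so identical seeds give bitwise-identical runs.
* One master seed fans out to named sub-seeds (shuffling, encoding,
  readout initialization) via a small integer hash kept below $2^{31}$, so
  each component can be re-run independently.

## Problem sizes

The test-suite sizes are chosen for a single CPU: unit oracles run on
single neurons or chains of at most 3 stages over 5–20 s of simulated
time; learning demonstrations use 16–24 px canvases with 2–4 kernels and a
few thousand simulated milliseconds; the end-to-end multi-objective run
uses a 32×32 canvas, one 5×5×8 layer, 20 training and 32 test sequences at
100 ms of observation per frame, and reaches joint accuracy ≈ 0.81 against
a 0.25 chance level in a few minutes.  Scaling the observation time,
canvas and stack back to the full reference configuration changes none of
the code paths, only runtime.

## Known limitations

* The decay-ratio figure of the reference analysis (long-term vs
  short-term decay ≈ 2.4 from a shared starting potential) is not
  reproducible from the printed $\{a,b,c\}$ under any reset convention we
  could identify; `decayTime()` exposes the closed form and the comparison
  is left as a demonstration, not a test.
* Free-running periodic simulation exceeds the pathway calculus off the
  commensurate grid, as analyzed above; treat $\Phi$ as a lower bound on
  free-running rates.
* STDP under sustained rate coding saturates kernels when stimuli are
  thick relative to the receptive field and dwell longer than the pairing
  window; feature learning demonstrations therefore use thin, moving
  stimuli.
* The spiking path of the prediction module (learner neurons with
  section-lateral inhibition) is implemented and tested at the operation
  level, but classification uses the rate readout; no spike-domain
  fine-tuning is performed.
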