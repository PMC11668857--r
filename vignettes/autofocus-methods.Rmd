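---
title: "Reinforcement-learning autofocus on synthetic focal stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reinforcement-learning autofocus on synthetic focal stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A liquid-lens microscope focuses by changing a drive voltage rather than by
moving optics. Autofocus then becomes a sequential decision problem: observe
the current image, adjust the voltage by a discrete amount (or stop), and
repeat until the image is sharp. `focusrl` implements this problem end to
end: a simulator for voltage-indexed through-focus stacks, sharpness
measures, discrete voltage action sets, a shaped reward, an episodic
environment, a deep Q-learning agent, and classical bracketing searches as
baselines.

An episode ends with the lens at some voltage; the *deviation* is the
absolute difference to the true in-focus voltage. An episode is *successful*
when the deviation is at most 0.2 V (inclusive) and *accurate* when it is
exactly 0 V. With the default 0.1 V resolution the success zone spans five
frames of a stack.

## The focal-stack simulator

A stack is rendered from a texture image: frame $i$ is the texture convolved
with an isotropic Gaussian point-spread function of width

$$\sigma(i) = \sigma_0 + s\,|i - i_\ast|$$

pixels, where $i_\ast$ is the in-focus frame, plus additive Gaussian sensor
noise clipped to $[0,1]$. Defaults: $\sigma_0 = 0.5$ px, $s = 0.3$ px/frame,
noise SD 0.01, 100 frames of 224×224 pixels at 0.1 V per frame starting at
35 V. This linear-σ model is the simplest unimodal defocus model consistent
with a defocused–focused–defocused sweep; it is a stand-in for real optics,
whose voltage-to-blur mapping is instrument specific.

The blur is applied in the Fourier domain with the exact Gaussian transfer
function $\exp(-2\pi^2\sigma^2|f|^2)$ under periodic boundary conditions.
This choice is load-bearing: the transfer function is strictly decreasing in
$\sigma$ at every non-zero spatial frequency, so every gradient-style
sharpness measure of a noiseless rendered stack is *strictly* unimodal in
the frame index — a property the tests rely on and that truncated spatial
kernels violate at heavy defocus.

Three texture families emulate common sample types: `regular_grid`
(high-contrast two-level periodic pattern), `bar_target` (grouped parallel
bars of varying pitch) and `speckle` (band-limited granularity). Patterns are
rescaled to an exact Michelson contrast (0.9 for the grid, 0.5 otherwise).
The grid period is kept at `size/8` or coarser: under heavy defocus a purely
high-frequency pattern's residual oscillation falls below double-precision
resolution against the mid-grey level, which would flatten the curve tails.

`build_dataset_list()` assembles lists of stacks, round-robin across
families, with the focus index drawn uniformly from the central 80% of the
sweep so both defocus flanks are present. `augment_dataset_list()` expands a
list with mirrored and gamma-adjusted copies, emulating the practice of
building many training stacks per sample from few acquisitions.

What the simulator does *not* emulate: asymmetric or field-dependent
point-spread functions, illumination drift, hardware response dynamics,
hysteresis, or sensor artifacts beyond white noise. Tests passing on
synthetic stacks therefore demonstrate the correctness of the algorithms and
the learnability of the control policy under idealized imaging, not
performance on any physical instrument.

## Action sets

An action multiplies the 0.1 V resolution by a signed integer control
factor; factor 0 is the stop action. Two constructions are provided for an
odd set size $n_A \ge 3$ with base $b \ge 2$:

* logarithmic: $\{0, \pm b^j\}$ for $j = 0, \dots, (n_A-3)/2$,
  e.g. $(-25,-5,-1,0,1,5,25)$ for $b=5$, $n_A=7$;
* multiple: $\{0, \pm 1\} \cup \{\pm kb\}$ for $k = 1, \dots, (n_A-3)/2$,
  e.g. $(-10,-5,-1,0,1,5,10)$.

For $b = 2$, $n_A = 7$ the two coincide. `check_action_space()` accepts a
configuration when the largest factor does not exceed half the state range,
$b^{(n_A-3)/2} \le n_S/2$; a literal logarithmic-inequality variant of this
rule rejects standard configurations such as $(b=5, n_A=7)$ on 100 frames,
so the bound on the largest factor is the definition used. Boundary moves
clip rather than error — a physical lens saturates at its voltage limits.

## The shaped reward

Each step the agent receives a sum of four gated components with defaults
$\alpha = 100$, $\beta = 30$, $\mu = 200$, $\delta = 100$ (magnitudes chosen
so no single component dominates):

* **sharpness** — under the default `corrected` orientation,
  $-\alpha(1 - F_c)$ with $F_c$ the per-stack min–max normalized sharpness:
  zero penalty at the sharpest frame, $-\alpha$ at the least sharp. The
  `literal` orientation $-\alpha F_c$ (the transcription that maps sharpness
  itself to $[-\alpha, 0]$) is kept behind a flag; it rewards defocus along
  the trajectory and is used by the ablation study (below).
* **time step** — $-\beta\,\ln(n/\beta)$: positive while $n < \beta$, zero
  at $n = \beta$, increasingly negative beyond.
* **stop** — $+\mu$ only when the agent stops within the 0.2 V success
  window (the Done flag).
* **extreme image** — $+\delta$ at the stack's ground-truth sharpest frame
  and $-\delta$ when normalized sharpness is at most 0.05.

Two design points deserve spelling out, because each admits a degenerate
alternative:

**Scope of the δ bonus.** If $+\delta$ is granted on every step spent at the
sharpest frame (`extra_scope = "every_step"`), then under the corrected
orientation an agent can collect $\delta$ indefinitely by loitering at
focus: the discounted loiter value $\delta/(1-\gamma) = 1000$ dwarfs the
one-shot stop payoff $\mu + \delta = 300$, and trained agents demonstrably
never stop. Granting the bonus only on the stop step
(`extra_scope = "stop_only"`, the default used by the learning experiments)
removes the exploit while preserving the intended effect — a premium for
stopping exactly at the sharpest frame. Under the literal orientation the
exploit self-cancels because $\alpha = \delta$ exactly offsets the bonus at
the peak.

**Step count is not observed.** The time component is positive for
$n < \beta$; if the policy could condition on $n$, postponing the stop to
harvest those early positive rewards would be optimal (the discounted
forfeited stream exceeds $(1-\gamma)\mu$ until $n \approx 11$). The
environment therefore supports a step-count feature but the learning
experiments exclude it: an image-only policy cannot represent deliberate
stalling, and empirically trained agents stop in well under $\beta$ steps.

## The environment

`af_env()` samples a stack uniformly from the list at each reset and a start
frame uniformly over the whole sweep (the success zone is not excluded).
Non-stop actions move the index with boundary clipping; episodes truncate at
50 steps. By default the stop action always ends the episode. The ablation
study instead uses `done_gated_termination = TRUE` — only a *correct* stop
terminates and an incorrect stop is a counted no-op — because a sharpness
reward bounded above by zero makes immediate stopping optimal under a
stop-anywhere contract, and "never terminates" is then unobservable for the
component-ablated variants it characterizes.

**Observation features.** The defocus model is symmetric: frames at
$i_\ast \pm d$ have identical blur, so a single frame carries no information
about the *direction* of defocus on unseen samples, and no memoryless
single-frame policy can exceed roughly coin-flip directional performance.
Focusing is intrinsically a sequential-information problem. The environment
therefore offers, besides the current frame: the pixel/feature difference to
the previous frame and a one-hot of the previous action — together they let
a policy infer whether its last move helped and hence which side of focus it
is on. The learning experiments use `frame + diff + prev_action`.

## The agent

`train_dqn()` implements value-based deep reinforcement learning: an
$\varepsilon$-greedy behavior policy (linear decay 1 → 0.05 over half of
training), a uniform experience replay of compact transition references, a
periodically synchronized target network, double-Q targets (online argmax,
target value), 3-step returns, Huber loss on rewards scaled by 0.01, and
Adam (the fused update runs in compiled code). Training is deterministic
given the seed. Divergent (non-finite) losses abort with a diagnostic.

**Observation encoder.** On one CPU, training a convolutional network end to
end is not affordable at useful step counts, while an unconstrained dense
network on raw pixels memorizes the training stacks: it reaches near-perfect
training success and 0% held-out success, because pixel coordinates of
specific textures — not blur — are the easiest features to latch onto. The
package's `randconv` encoder supplies the convolutional inductive bias
without the training cost: a fixed, seeded bank of zero-mean random 5×5
filters at three dyadic scales; each filter's rectified response is
average-pooled over the frame, and each band contributes its energy, its
log-energy (band *ratios* become additive), and its within-scale fraction
(a scale-free spectral shape). Defocus attenuates each band as a smooth
function of $\sigma$, so the embedding encodes blur level in a form that
transfers across textures — in the spirit of random-feature methods. The
bank is never trained; the Q-head (fully connected, 128 and 64 hidden ReLU
units) is. Frame embeddings are precomputed per stack, which also makes
training fast: replay stores only integer frame references and batches are
gathered by column indexing.

**Tie-breaks and determinism.** Greedy action selection breaks ties toward
the lowest action index; evaluation of a fixed agent on a seeded list is
fully deterministic. All randomness flows from R's global RNG, fanned out to
components by a counter-based scheme (`fan_seed`) so adding a consumer never
perturbs other streams.

## Classical search baselines

`sweep_search()` probes every frame (the oracle argmax).
`golden_section_search()` and `fibonacci_search()` shrink a bracket on the
frame lattice — golden-ratio interior points in the first case, the
Fibonacci offset schedule (with virtual $-\infty$ lattice padding, so edge
clamping never wastes probes) in the second — until the bracket is at most
`tol_indices` (default 2) frames wide, then probe the few remaining interior
frames. All probed values are cached, so no frame is captured twice, and on
a strictly unimodal curve the returned index is the exact global argmax.
Derived probe bounds, asserted by the tests: golden-section at most
$2 + \lceil \log_\phi((N{-}1)/\mathrm{tol}) \rceil + \mathrm{tol} + 1$
(13 for $N = 100$), Fibonacci at most the smallest $k$ with $F(k) \ge N$
(12 for $N = 100$; 10 observed).

A probe here is one sharpness evaluation, i.e. one image capture at a lens
setting. Published step counts for bracketing autofocus methods vary with
the termination tolerance and with what is counted as a step; every report
produced by `run_baseline_comparison()` states this convention in its
`"convention"` attribute rather than assuming one.

## The experiment runners and desk-scale sizes

`run_action_space_study()`, `run_sampling_study()`, `run_ablation()` and
`run_generalization()` train and evaluate agents over the corresponding
condition grids and return stamped data frames (config hash + seed;
identical configuration and seeds regenerate identical rows).
`run_ablation()` trains the five reward variants — sharpness only; +stop;
+time; +extra; all four — under done-gated termination and the literal
orientation: with the corrected orientation the sharpness-only agent's
stop-vs-loiter values tie at the peak (both zero), making its termination
behavior an artifact of approximation noise, whereas under the literal
orientation the variants separate cleanly. Observed behavior at desk scale:
the variants without a stop bonus (sharpness only, +extra, +time) fail to
stop autonomously — the heavily defocused plateau is a near-zero-cost region
to wander in, while visiting the focus region is expensive — and the
variants carrying the stop bonus terminate, the full hybrid reward in the
fewest mean steps. The ablation also grants the δ bonus on the stop step
only (the `extra_scope` argument): per-step δ penalties on the blur plateau
would otherwise push even the stop-free variants into terminating.

The package's study sizes: stacks of 100 frames at 64×64 for training
experiments (224×224 is supported and used for the simulator's conformance
checks), lists of 6–10 stacks, 12 000–45 000 environment steps depending on
the study, evaluation over 150–1000 episodes. These are the configurations
the test suite executes; larger runs only require changing the
corresponding arguments.

## Numerical choices and degenerate inputs

* Success threshold comparisons carry a `1e-12` absolute slack so a 0.2 V
  deviation computed as `2 * 0.1` passes the inclusive boundary.
* Min–max normalization of a constant sharpness curve is an error
  (degenerate curve), as is a texture smaller than 8 px or a contrast
  outside $(0, 1]$.
* `which.max` tie-breaking (lowest index) is relied on for reproducibility.
* The compiled Q-update runs with flush-to-zero/denormals-are-zero set (and
  restored on exit): Adam's decaying moments otherwise reach subnormal
  magnitude for rarely active inputs and the resulting microcode-assisted
  arithmetic slows training several-fold, with no measurable effect on the
  learned policies.
* Stacks store intensities in $[0,1]$; on disk frames are 8-bit PNGs, so a
  write/read round trip is exact up to 1/255 per pixel, with voltages and
  indices exact via the JSON sidecar (0-based frame numbering on disk,
  1-based indices in R).

## Limitations and scope

* The simulator's linear-σ Gaussian model omits the asymmetries and
  aberrations of real optics that can make the two defocus directions
  visually distinguishable; real systems may therefore need less sequential
  information than the symmetric simulator suggests, not more.
* `focusrl` does not attempt to reproduce hardware-measured performance
  figures reported for physical liquid-lens systems — e.g. a mean of 3.15
  time steps, a 97.2% success rate, an RMSE of 2.85×10⁻³ V, ablation score
  tables, or fixed golden-section/Fibonacci step counts of 15 and 8. Such
  values depend on the captured stacks of the specific instrument, on
  training details that are not public, and on an acquisition-system
  step-counting convention that cannot be recovered; no single tolerance
  setting reproduces both of those search step counts simultaneously. The
  test suite instead verifies property-level behavior: exact action-set
  constructions, simulator conformance, search optimality with bounded
  probes, reward identities, scaled-down learning success against search
  baselines, ablation termination patterns, and the generalization benefit
  of training on mixed samples.
* Training at the full 224×224 / 50-stack scale is supported by the same
  code paths but is not exercised by the default test suite.
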