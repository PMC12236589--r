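---
title: "A hippocampal-entorhinal loop model: path integration, sensory recall, and planning on the grid manifold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hippocampal-entorhinal loop model: path integration, sensory recall, and planning on the grid manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gridnav` implements a system-level model of how the medial entorhinal
cortex (MEC) and hippocampus (HC) could jointly support localization,
cue-triggered recall of goal locations, and planning of unvisited routes.
The model has three interlocking parts.

**1. A single recurrent network with auxiliary input and output nodes.**
All cell populations live in one state vector $z$ updated as

$$ z_{t+1} \;=\; \alpha \odot z_t \;+\; (1-\alpha) \odot
   \big( \mathrm{inject}(u_t) + W\, f(z_t) \big), $$

where $W$ is a single unconstrained recurrent matrix over all populations,
$f$ is rectification at zero (model rates are $f(z)$, non-negative),
$\alpha \in [0,1]^d$ is a *learnable per-unit* forgetting vector
(parameterized through a sigmoid), and $\mathrm{inject}(u_t)$ places raw
input values directly into the coordinates of the input populations - there
is no learned input or output projection; sub-blocks of $W$ play those
roles. Populations: grid cells (GC; supervised outputs, initialized from
ground truth at $t=0$ only), spatially modulated sensory cells (SMC; both
inputs and supervised outputs), head-direction and speed cells (inputs
only), and hidden units that are neither (the place-cell candidates).

**2. Ground-truth tuning maps.** Grid modules have periods
$\ell_i = \ell_0 s^i$; by default six modules with the smallest spacing at
30 cm and scale factor $s=\sqrt e$ (the 2-D optimum; $s=e$ in 1-D). Each
cell's map is a sum of Gaussian fields of sd $\sigma_i$ on a triangular
lattice translated by a per-cell phase offset; the spacing-to-field-size
ratio is 3.26 with the field *diameter* read at two standard deviations,
so $\sigma_i = \ell_i / (4 \cdot 3.26)$. SMC tuning is synthetic smoothed
rectified spatial noise with a configurable correlation length - a
stand-in for spatially informative sensory embeddings, not a model of any
particular sensory system.

**3. An analytic and a learned planner on the grid torus.** A module's
population state is summarized by a phase on the torus; displacement
decoding wraps phase differences into $(-\pi,\pi]$ (shortest wrap; the
antipodal tie resolves to $+\pi$), maps them through the lattice basis,
and averages across modules. A Markov transition matrix over discretized
phases supports sequential planning, and a learned planner subnetwork
drives the frozen base network with internally generated speed and
head-direction activity.

# Training protocol

Networks are trained by backpropagation through time (hand-written, on
BLAS matrix operations) with Adam, on freshly simulated 5 s trajectories
(dt = 0.05 s, i.e. 100 timesteps) each gradient step. The GC population is
supervised to path-integrate: it receives its ground-truth rates only in
the initial state and must track them from noisy self-motion input. The
SMC population autoencodes: its inputs are masked (and noisy) sensory
samples; its targets are the clean patterns. Masking draws a per-trajectory
effective fraction $f \sim U(0, r_\mathrm{mask})$ and zeroes independent
Bernoulli($f$) entries across time and cells, in both inputs and the
initial GC/SMC state.

Three training choices matter and are deliberate:

* **Rate supervision.** The loss compares $f(z)$ of the output coordinates
  with the non-negative target rates (config `supervise = "rate"`).
  Supervising $z$ itself forces exact zeros over the large silent regions
  of a sharp grid code and removes the subthreshold range the units need
  for velocity-conjunctive computation; in our experiments this choice is
  the difference between learning path integration and stalling at the
  variance floor.
* **Horizon curriculum.** The full-scale task (5 s rollouts from scratch)
  gives almost no early gradient signal at desk scale: the short-horizon
  component of the error is 1/100 of the loss. The default schedule
  therefore trains the first ~60% of steps on 1 s segments (where the
  update rule is learned) and the remainder on the full 5 s horizon at a
  reduced learning rate (where long-horizon stability is learned).
  Training *schedules* are exposed in full via `curriculum`.
* **Contraction noise.** Small Gaussian state perturbations
  (`state_noise`, default 0.02) are injected during training rollouts only.
  They force the learned dynamics to contract back onto the represented
  manifold, which is what keeps open-loop integration stable beyond the
  trained horizon.

# Desk-scale study conditions

All quantitative tests run at a "desk scale" chosen to fit a single CPU:
a 1.5 m x 1.5 m arena; 2 cm ratemap bins for training and decoding (1 cm
bins for the grid-geometry measurements); foraging at mean speed 15 cm/s
with heading persistence 0.9 and a run/pause process (~25% time paused;
trajectory statistics are not published for the source experiments, and
pauses turn out to be required for any network that must *hold* a state,
see below). The four fitted configurations:

* **Path integrator**: 2 modules x 64 grid cells, 32 head-direction and 16
  speed cells, 6800 gradient steps (batch 32) over the horizon curriculum,
  continuous foraging (no pauses - this experiment probes pure
  integration; the 2-module stack is the reference scaled-down setting).
* **Planner base**: as above but 4 modules x 32 cells. Two desk-scale
  modules leave strong approximate aliases in the joint code (positions
  ~1 m apart share near-identical rate vectors), which wrecks
  nearest-neighbour decoding and planning; four incommensurate periods
  remove them at the same cell budget.
* **HC-MEC loop**: 4 modules x 16 GC, 64 SMC (correlation length 15 cm),
  32+16 self-motion cells, 96 hidden units; masking ramp (0.3 early, the
  nominal ratio for the final ~60% of steps), 25% cold-start episodes,
  ~3100 steps. Used for the recall experiment and the full-loop planner.
* **Masking-trend pairs**: a smaller HC-MEC (4 x 12 GC, 32 SMC, 64
  hidden, ~1400 steps), three seeds at each of r_mask 0.1 and 0.9.

The planner trains on 128 fixed start/goal pairs drawn from 1 s
trajectories and is probed on pairs from 10 s trajectories. These sizes
are the package's own scaled-down study conditions; the full-scale
configuration (six modules, 512 hidden units, nine masking ratios) is
reachable through the same configs but is not exercised by the test
suite.

What the synthetic generator does *not* emulate: real sensory statistics
(SMC maps are smoothed noise, not vision), boundary/border cells and
obstacle avoidance, non-rectangular arenas, and 3-D navigation. Passing
tests therefore show that the mechanisms work as specified on clean
synthetic tuning, not that they survive real sensory data.

# Numerical and design choices

* **Coordinates and bins.** The arena is $[0,W)\times[0,H)$ cm, origin
  lower-left; bins are half-open, x index fastest in flattened order;
  nearest-neighbour decoding breaks exact ties toward the lowest flattened
  bin index.
* **Field measurement.** Field centers are local maxima above half the map
  peak with minimum separation $2\sigma$, refined by per-axis parabolic
  interpolation of log-rate (exact for Gaussian fields); fields within
  $2\sigma$ of the border are discarded; spacing is the median
  nearest-neighbour center distance; field size is $4\hat\sigma$ from a
  log-rate regression on squared distance.
* **Trajectory model.** Wrapped first-order autoregressive heading (turn
  sd $(1-\rho)\pi$), Rayleigh speeds rescaled to the configured mean, a
  two-state run/pause process (~17% of time paused at the defaults, as in
  natural foraging), reflective walls. Recorded headings/speeds describe
  the *realized* displacement (reflections mirror the step), so
  self-motion input is always consistent with the trajectory. The pauses
  are load-bearing: a network that never experiences speed ≈ 0 cannot
  hold a stationary grid state, and the planner's hold-at-goal objective
  then has no solution.
* **Masking draws.** The exported masking operation draws one effective
  fraction $f \sim U(0, r_\mathrm{mask})$ per call. The training protocol
  draws $f$ independently per masking target (SMC/DIR/SPD inputs, GC/SMC
  initial state) within each trajectory, so that some trajectories lose
  nearly all of one pathway while the others survive - the condition under
  which cross-population associations (sensory-anchored path integration,
  cue-triggered recall) acquire training pressure.
* **Sequential planning mechanics.** The planning vector starts with equal
  mass on the start and target bins and diffuses through the row-stochastic
  transition matrix. Two readout details are our design (the source
  narrative leaves them open): the target bin is re-marked by *adding* the
  running maximum after each update - a persistent source whose
  renormalized field keeps a stationary gradient (a pure clamp provably
  flattens to the uniform vector and stalls antipodal plans) - and the
  walker advances only when a neighbour strictly beats its current bin
  (the clamped target, which can tie but never strictly win, is entered
  whenever adjacent). With these rules planned path lengths equal graph
  geodesics for all pairs on rings up to $N = 32$ and tori up to $N = 8$;
  on larger tori, pairs whose displacement along an axis is exactly $N/2$
  (two equivalent geodesics) can cost one extra step, because the two
  interfering diffusion fronts delay the walker's commitment.
* **Multi-scale contraction.** The inequality for guaranteed contraction
  is typographically mangled in the source text; we implement the
  reconstruction $m > k + (1-s^{-k})/(s-1)$, which reproduces both stated
  corollaries ($m>k$ at $s=e$ in 1-D, $m>k+1$ at $s=\sqrt e$ in 2-D).
  Empirically the $m>k$ form is *not* sufficient at $k=m-1$: the averaged
  update $d_{next} = \tfrac1m\sum_i \ell_i\,\mathrm{round}(d/\ell_i)$ is
  piecewise constant in $d$ and has attracting fixed points (for the
  default 6-module stack, e.g. $d^\ast \approx 939.7$ cm), where the
  remaining distance stalls; most draws with $k=m-1$ hit such points, and
  smaller step fractions do not escape them. One extra scale of slack
  ($m > k+1$) removes every such failure in our Monte-Carlo runs in 1-D
  and 2-D alike; the tight sufficient condition we derive along the source
  text's own argument is $m > k + s(1-s^{-k})/(s-1)$. The acceptance suite
  keeps the source text's literal claim, which therefore stays red on the
  1-D clause.
* **Place-cell criteria.** The published thresholds (mean rate 0.01,
  spatial information 20) reference an unavailable score definition; with
  the Skaggs bits-per-activation form used here the ceiling is
  $\log_2(\#\mathrm{bins})$, so 20 is unreachable. The defaults keep the
  published numbers for reference; analyses calibrate `min_sic = 1.5`
  bits (an ordinary in-vivo place-cell value). The tested behaviour is the
  *trend* - more identified place cells at high masking than at low - not
  the absolute count.
* **Optimization.** Adam ($\beta_1 = 0.9$, $\beta_2=0.999$), global
  gradient-norm clip at 5, learning rate 3e-3 (a quarter of that in the
  long-horizon phase), $\alpha$ initialized at 0.9. The optimizer and its
  settings are not specified by the source; these are ordinary choices.
* **Planner.** Planner leak fixed at 0.5; planner dimension 64; loss is
  the MSE between current and goal GC rates over all timesteps; the base
  network is frozen (our reading of "connect a planning network to a
  pre-trained GC network"); projections from SMC and hidden units into the
  planner are structural zeros, asserted bitwise in tests.

# Training protocol aids at desk scale

Two protocol elements exist purely because of the scale gap to the source
experiments, and both are off by default outside the test configurations:

* **Masking ramp**: networks nominally trained at r_mask = 0.9 spend the
  early curriculum at 0.3. At a fixed 0.9 the desk-scale networks never
  leave the variance floor, so nothing downstream is measurable.
* **Cold-start episodes** (`cold_start_prob`): a fraction of training
  trajectories zero the whole GC initial state, forcing localization from
  the sensory stream. Under the plain protocol a complete GC blackout
  essentially never occurs (the per-cell masking fraction is at most
  0.9), and without such episodes the cue-to-grid recall pathway acquires
  no training pressure at this scale: recall converges in SMC coordinates
  but the GC trace stays at chance. The source experiments reach the same
  pathway through scale alone, so passing recall here demonstrates the
  mechanism, not its unaided emergence.

# Known limitations

Desk-scale grid codes with few modules are brittle: occasional
nearest-neighbour decode glitches to aliased positions are visible as
heavy tails in the error distribution (medians are the meaningful
aggregate), and the learned planner's generalization from 1 s training
pairs to 10 s probe pairs depends on how far outside the trained
displacement range the probes fall; the planner reliably approaches
targets inside its trained range but under-reaches distant ones, and in
the full-loop configuration the episodes that derail in grid coordinates
also decouple the sensory-decoded path from the grid-decoded one, giving
the decoded-position discrepancy a heavy tail. The path-integration
error of the 2-module reference network likewise has a heavy aliasing
tail: its 10 s median sits within a centimetre or two of the smallest
field radius, on either side depending on the training realization. Recall converges onto an attractor a few centimetres from the cued
location, so the fraction of queries inside the strict 2-sigma radius
sits well below one even when every query curve collapses from ~100 cm to
~5 cm. The place-cell count *trend* across masking ratios does not
reproduce at this scale at all under the Skaggs criteria: hidden units
inherit spatial modulation from their grid/sensory drive at every masking
level (at r_mask = 0.1 slightly more units pass than at 0.9), whereas the
source result plausibly rests on participation sparsity in a 512-unit
reservoir. Training and recall quality at this scale vary noticeably
across seeds. None of the analytic planning components share these
caveats; they are exact to the stated tolerances.

# Reproducing the headline measurements

`scripts/acceptance.R` regenerates the grid-geometry measurements (field
spacing of the smallest module and the spacing/field-size ratio) from a
freshly generated hierarchy under the reference configuration and writes
them as JSON; `README.md` shows a worked example with the numbers the
package prints.
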