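---
title: "Modelling and fitting the light-entrainable cellular circadian clock"
author: "circlum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting the light-entrainable cellular circadian clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(circlum)
```

## The model

Cultured clock-reporter cells behave as a dish of thousands of *uncoupled*
circadian oscillators: each cell keeps its own rhythm, while the
plate-reader signal is the sum over the well.  In constant darkness the
cells drift apart in phase and the *population* amplitude decays, even
though each cell's own amplitude is undiminished; a light-dark (LD) cycle
pulls the phases back together.  `circlum` models this with a minimal
stochastic oscillator per cell and an average over cells.

Each cell carries a three-variable transcription–translation negative
feedback loop — mRNA $M$, cytoplasmic protein $P$, nuclear repressor $R$ —
closed by a protein-sequestration activation function.  The repressor binds
an activator (total concentration $A$) with 1:1 stoichiometry and
dissociation constant $K$; the free-activator fraction is

$$f(R, A, K) = \frac{A - R - K + \sqrt{(A - R - K)^2 + 4AK}}{2A},$$

which for the tiny dissociation constants that permit oscillations
($K \le 10^{-4}$) is indistinguishable from its $K \to 0$ piecewise limit
$f = \max(1 - R/A,\, 0)$.  The package runs the piecewise limit by default
(`clock_parameters(K = NULL)`); `sequestration_activation()` and a
trajectory-level test verify the convergence.

After nondimensionalization (production rates scaled to 1), the single-cell
dynamics with light input and noise are

$$
\begin{aligned}
\dot M &= f(R, A) - d_M M + i\,I(t) + \sigma \xi_M,\\
\dot P &= M - d_P P + \sigma \xi_P,\\
\dot R &= P - d_R R + \sigma \xi_R,
\end{aligned}
$$

with $I(t) \in \{0, 1\}$ a binary lighting protocol, $i$ the light
sensitivity (the additive light drive models the light-driven clock-gene
induction characteristic of the zebrafish clock), $\sigma$ the noise
intensity, and $\xi_*$ independent white noises.  A cell's reporter
luminescence is $L_j = f(R, A)$, and the well signal is the average
$L = \frac{1}{n} \sum_j L_j$ over $n$ independent cells ($n = 30{,}000$
mirrors a well; $n = 1{,}000$ is used during fitting, where the difference
to the full average is negligible relative to the fitting error).

## Numerical scheme

The stochastic system is integrated by fixed-step Euler–Maruyama
(default $dt = 0.01$ h; $0.05$ h during fitting, where the same step is
used for generating and fitting synthetic data so that discretization
bias cancels).  The deterministic system ($\sigma = 0$) uses classical RK4
at the same steps; a step-halving test keeps the discrepancy below
$10^{-3}$.  The integrators live in compiled code; each cell draws from an
independent counter-based random stream keyed by `(seed, cell)`, so
trajectories are reproducible and unaffected by how many other cells are
simulated or recorded.

State variables are *not* clamped at zero: the additive noise may push them
transiently negative, in which case the piecewise activation is evaluated
as written (giving $f > 1$ for $R < 0$).  Nothing in the formulation
forbids this, the excursions are brief at the fitted noise levels, and
clamping would bias the population mean; the behavior is documented rather
than hidden.

Output is recorded on a regular grid (default 40 min), matching the
plate-reader cadence of the recordings the model emulates; the
integration step is nudged to the nearest exact divisor of the sampling
interval, so recorded times land exactly on the grid and any two
simulations sharing the same nominal step share the same discretization.  Lighting
protocols are piecewise-constant with half-open segments $[start, end)$:
a switch instant belongs to the new segment, so sampling exactly at
lights-on reads light.  Recordings start at the beginning of a dark phase
by default.  Queries past the protocol's end hold the final level and
warn, which tolerates fitting windows that overrun by one sample.

## Normalization and goodness of fit

Raw well traces differ by arbitrary scale and offset (reporter load,
optics).  Untreated wells are normalized trace-by-trace to Z-scores,
$z(x) = (x - \bar x) / S_x$, and replicate wells averaged.  For
compound-treated wells the change in mean and variance *is* part of the
effect, so the adjusted Z-score rescales each trace relative to the control
group: $z_d(x) = \frac{x - \bar x}{S_x} \frac{S_d}{S_c} + \frac{\bar x_d -
\bar x_c}{S_c}$, with group statistics being means of per-trace means and
standard deviations; for the control group this reduces exactly to the
plain Z-score.  Model output is normalized by the statistics of the
*control-parameter* simulation, the model-side counterpart of the adjusted
score (population averages are nearly noise-free, which collapses the
adjusted form to that simple ratio).

Fit quality is the model efficiency coefficient
$E_f = 1 - \sum_i (x_i - \hat x_i)^2 / \sum_i (x_i - \bar x)^2 \in
(-\infty, 1]$: 1 is perfect, 0 is "no better than the data mean", and
$E_f \le 0$ flags a failed fit.

## The four-stage fitting pipeline

Stochastic population simulations are expensive, so the pipeline spends
them only where needed:

1. **Circadian screen ($C_1$).**  With $\sigma = 0$ and the degradation
   rates tied ($d_M = d_P = d_R = d$, the regime most likely to
   oscillate), differential evolution (DE) minimizes
   $C_1 = (T_{DD} - 24)^2 + (T_{LD} - 24)^2 + (P_{LD} - P_{LDs} + 12)^2$,
   where $T_{DD}$ is the free-running period, $T_{LD}$ the period under a
   12:12 LD cycle, and $P_{LD}$, $P_{LDs}$ the entrained peak phases under
   the cycle and the cycle offset by half a period.  Phases are peak times
   of the deterministic luminescence after a 5-day transient, modulo 24 h,
   and the phase term is wrapped to $(-12, 12]$ before squaring (the
   operational definition of phase is a package choice; the quantity is
   otherwise underdetermined).  Non-oscillatory candidates score a penalty
   of $10^6$, far above any attainable squared error.  The optimization is
   repeated independently (50 times at study scale) to produce a
   *population* of distinct circadian parameter sets.

2. **Noise from damping ($C_2$).**  Cell-to-cell desynchronization makes
   the population amplitude decay in darkness, and faster for larger
   $\sigma$.  The damping ratio $d_{data}$ of the recording (damped-sine
   fit to the first six days, the constant-darkness portion of the
   canonical varied-lighting protocol) is matched by fitting $\sigma$
   per member — all other parameters frozen — minimizing
   $C_2 = (d_{data} - d_{model})^2$, with $d_{model}$ measured the same
   way on the simulated population released into darkness after three
   12:12 LD cycles.

3. **Trace fit ($C_3$).**  DE over $(A, d, i, \sigma)$ (equal degradation
   kept) minimizes the mean squared error between the normalized data and
   the normalized simulated population mean, initialized with the stage-2
   population.  Initial conditions come from a 10-day LD burn-in.  Before
   each stochastic evaluation the deterministic model is screened for
   sustained free-running oscillations (untreated cells demonstrably
   sustain them); failures return the penalty without touching the
   stochastic model.

4. **Compound series ($C_4$).**  For treated cells neither sustained
   free-running rhythms nor equal degradation can be assumed, so both
   constraints are dropped and the cost becomes the sum of the LD-segment
   and DD-segment mean squared errors.  The initial state is *fixed*
   throughout: the untreated model's state at a light-to-dark transition.
   Concentrations are fitted iteratively from control to the highest dose,
   each step seeding its DE with the previous step's final population;
   fits with $E_f \le 0$ are flagged excluded.

The DE optimizer (rand/1/bin, mutation 0.7, crossover 0.9) is written in
the package.  Stochastic costs are evaluated under *common random
numbers*: all candidates of a generation share a seed, and the surviving
population is re-scored each generation, so selection compares like with
like and no member survives on a lucky noise draw.  Parameter bounds —
$A \in (0, 5]$, $d \in (0.01, 2]$ /h, $i \in [0, 0.2]$,
$\sigma \in [0, 0.5]$ — bracket circadian-plausible dynamics and are
configurable.  The light-sensitivity bound deserves a note: on the
nondimensionalized amplitude scale of this model, any $i$ much above 0.1
floods the loop with repressor and silences the reporter under *every*
lighting schedule in the box, so a wide bound would hand the optimizer a
vast penalty plateau with a thin feasible island near $i \approx 0.02$ and
stage-1 runs would stall on the plateau.  $[0, 0.2]$ still spans
everything from no light input to complete light repression.  Stage-1
runs additionally stop early on stagnation and are retried with a fresh
seed, which clears the occasional run that converges to a 24-h oscillator
that ignores the light schedule (the phase-tracking term of $C_1$ is flat
there).  Stage 3
pads its initial population to 16 members with 10% lognormal jitter around
the stage-2 solutions: the normalized-trace cost has a shallow curved
valley correlating $A$, $i$ and $\sigma$, and a small unjittered
population tends to stall partway along it.

## The synthetic plate generator

No recordings ship with the package; `generate_plate()` produces
pseudo-experimental plates with known ground truth instead.  Each well is
an independent population simulation at its ground-truth parameters,
sampled every 40 min, distorted by a per-well affine map (scale in
$[0.5, 2]$, offset in $[0, 1]$, emulating between-well reporter
variability) plus additive Gaussian measurement noise (default sd 5% of
the trace sd; the model itself adds none, but real plates do).  A JSON
manifest captures every seed and parameter, and `regenerate_plate()`
rebuilds the CSV bit-exactly.

The default ground truth, `reference_parameters()` — $A = 2$,
$d = 0.1885$ /h, $i = 0.02$, $\sigma = 0.02$ — was chosen once, before any
fitting experiments were scored, to express the canonical phenotypes of
this cell system: a deterministic free-running period of 24.0 h;
entrainment by 12:12, 15:15 and 10:10 LD cycles with phase tracking of a
half-cycle schedule shift; complete repression of the rhythm under
constant light; strong (type 0) resetting by 12-h light pulses; and a
population damping ratio of about 0.015/h in darkness (amplitude fading
over a few days while single cells keep oscillating), with LD-peaked and
DD-flattened single-cell phase histograms.  The light sensitivity sits in
a genuinely narrow window: at this amplitude scale, $i \gtrsim 0.04$
flattens the rhythm even under the LD cycle, while $i \lesssim 0.01$
entrains too weakly to reset strongly.  The canonical fixture
(`fig2a_fixture()`) is a 16-well plate under 6 days darkness, three 12:12
LD cycles, and 3 days constant light (288 h).

What the generator does *not* emulate: instrument artifacts
(plate-movement gaps, integration windows, cross-talk), drift in the
affine distortion over time, intercellular coupling, and graded light
intensities.  Passing tests therefore demonstrate internal consistency of
model, pipeline and analyses — not that real recordings of any particular
cell line would yield the same parameter values.

## Post-fit analyses

* **Phase response curve** (`phase_response_curve`): deterministic model,
  entrained then released into darkness; one 12-h pulse per onset phase;
  the shift is read on the 4th peak after pulse end (a package choice —
  shifts measured on the 3rd vs 5th peak agree within 0.5 h) against the
  unpulsed control, wrapped to $(-12, 12]$ and scaled by the model's own
  free-running period.  `prc_type()` classifies by the winding of the
  phase transition curve: wrapped increments of new phase around one old-
  phase cycle sum to $\approx 0$ (type 0, strong resetting) or
  $\approx 24$ h (type 1, weak); the rounded average slope is the label,
  and slopes near one half are refused rather than guessed.

* **Phase angle of entrainment** (`phase_angle_curve`): for each zeitgeber
  period $T$, symmetric $T/2{:}T/2$ cycles; after five transient cycles,
  the first population peak at or after a lights-on event gives the angle
  $-(t_{peak} - t_{on}) \cdot 24 / T$ (negative = peak lags lights-on);
  periods at which the rhythm does not adopt $T$ within 10% are reported
  missing rather than extrapolated.

* **Phase histograms** (`phase_histogram`): peak phases of retained
  single-cell traces within a window, 24 one-hour bins over $[0, 24)$,
  density normalized; cells contribute every peak they have in the
  window.  `circular_variance()` summarizes synchrony.

* **Parameter-ensemble PCA** (`pca_parameter_populations`): members of
  the final optimizer populations pooled, each parameter z-scaled across
  the pool (so rates and dimensionless parameters weigh equally), then
  projected; per-population location/spread reported as median ± MAD.
  Constant parameters are dropped with a message rather than crashing the
  decomposition.

## Problem sizes and reproducibility

Simulations scale linearly in cells × steps.  The package's tests and the
acceptance script run the pipeline at desk scale — 3–10 stage-1 runs
instead of 50, a few hundred to a thousand cells per stochastic cost, and
DE budgets of tens of generations — sizes at which every qualitative
property above is expressed and the whole suite completes on a laptop
CPU.  All randomness flows from explicit seeds: the same seed gives the
same plate, the same fit, and the same analysis, bit for bit.

## Known limitations

* The three-variable loop is minimal: no explicit light-driven gene
  states, no delayed feedback, no cell coupling; the additive light term
  cannot express graded intensity responses.
* After Z-normalization the absolute scale of $A$ is informed only by
  waveform shape, so $(A, i, \sigma)$ are correlated in the trace cost;
  recovery of $A$ to better than ~10–20% needs either plate-scale data
  (16 wells, $\ge 10^3$ cells) or external amplitude information.
* The equal-degradation constraint of stages 1–3 is a modelling
  convenience (it maximizes the chance of oscillation), not a biological
  claim; stage 4 drops it.
* Period and phase extraction are peak-based; spectral estimators are out
  of scope, so signals without clear peaks (heavy damping plus noise)
  yield missing values instead of estimates.
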