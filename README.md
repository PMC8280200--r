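# circlum

Stochastic modelling and fitting of the light-entrainable cellular
circadian clock from bioluminescence plate recordings.

## The problem

Clock-reporter cell lines (e.g. zebrafish PAC-2 cells carrying a
`per1b:luc` reporter) are recorded in multiwell plates for days under
programmed lighting.  Three phenomena dominate such recordings: the
population-level oscillation amplitude decays in constant darkness, a
light-dark (LD) cycle re-synchronizes the rhythm, and constant light
represses it.  The decay in darkness is not a property of single cells —
they keep oscillating — but of a *population of uncoupled oscillators*
drifting apart in phase.  Quantifying that requires a single-cell
stochastic model averaged over thousands of cells, plus a fitting
procedure frugal enough to run such simulations inside an optimizer.

`circlum` is for chronobiologists and modellers who want to fit this class
of model to plate recordings, run entrainment analyses on the fitted
oscillator, or generate realistic synthetic plates with known ground truth.

## The model

Each cell is a three-variable transcription–translation feedback loop
(mRNA `M`, protein `P`, nuclear repressor `R`) with protein-sequestration
activation, binary light input `I(t)` and additive noise:

    dM = [ f(R, A) − d_M·M + i·I(t) ] dt + σ dW_M
    dP = [ M − d_P·P ]              dt + σ dW_P
    dR = [ P − d_R·R ]              dt + σ dW_R

    f(R, A) = max(1 − R/A, 0)      (K → 0 sequestration limit)

A cell's luminescence is `f(R, A)`; the well signal is the mean over `n`
independent cells.  Fitting proceeds in four differential-evolution
stages: C1 deterministic circadian screen (24-h free-running period,
entrainment, phase tracking), C2 noise intensity from the population
damping ratio in darkness, C3 full trace fit with an oscillation screen,
C4 compound-series refits with relaxed constraints.  Fit quality is the
model efficiency `E_f = 1 − Σ(x−x̂)²/Σ(x−x̄)²`.

## Worked example

Generate a synthetic 4-well plate under the canonical varied-lighting
schedule (6 days darkness, three 12:12 LD cycles, 3 days constant light),
fit the model at desk scale, and inspect the result:

```r
library(circlum)

truth <- reference_parameters()
fx    <- fig2a_fixture(truth, seed = 5, n_wells = 4, n_cells = 300)
prot  <- concat_protocols(constant_protocol(0, 144),
                          ld_cycle(12, 12, 3),
                          constant_protocol(1, 72))

ctl <- clock_fit_control(n_cells = 300,
                         stage1 = list(n_runs = 4, n_pop = 20, max_gen = 60),
                         stage2 = list(n_pop = 5, max_gen = 6, n_cells = 300),
                         stage3 = list(n_pop = 12, max_gen = 20, tol = 0),
                         seed = 11)
fit <- clock_fit(fx$plate, prot, ctl)
print(fit)
#> Stochastic circadian clock model fit
#>   C3 cost: 0.03449   model efficiency E_f: 0.958
#> Clock oscillator parameters
#>   A = 2.421, d_M = 0.1864, d_P = 0.1864, d_R = 0.1864 (1/h)
#>   light sensitivity i = 0.02303, noise sigma = 0.02423
#>   activation: piecewise (K -> 0 limit)
```

The fitted degradation rate, light sensitivity and noise intensity land
near the generating values (A = 2, d = 0.1885, i = 0.02, sigma = 0.02; at
this reduced desk scale the activator concentration, the least
identifiable parameter after normalization, is ~20% high — plate-scale
fits tighten it).  `E_f = 0.96` says the simulated population mean
explains 96% of the variance of the normalized plate signal.  The fitted
oscillator then supports the entrainment analyses:

```r
prc <- phase_response_curve(fit$params, pulse_h = 12, n_phases = 12)
prc_type(prc)
#> [1] 0          # strong (type 0) resetting by 12-h pulses
phase_angle_curve(fit$params, T_values = c(20, 24, 30), n_cells = 500,
                  n_cycles = 12)
#>    T phase_angle
#> 1 20  -2.4351818
#> 2 24  -1.2535271
#> 3 30  -0.8759834
```

The phase angles say the population peak lags lights-on by 1.3 h under a
24-h cycle, with larger normalized lags for shorter zeitgeber periods —
the classic dependence of the entrained phase on cycle length.

`plot(fit)` overlays data and model with dark phases shaded; see the
vignette (`vignettes/clock-model-methods.Rmd`) for the model's
assumptions, the staged costs, and every numerical convention.

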