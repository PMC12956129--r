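---
title: "Solvent-exchange control: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvent-exchange control: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueproc)
```

# The device and what the software models

The processor this package controls is a two-container solvent-exchange
machine. Stock reservoirs (by default distilled water, 70% ethanol, absolute
ethanol) feed three peristaltic pumps that blend the next step's solution in
a *premix container*. A motorized ball valve then transfers the solution into
the *tissue container* by gravity; the specimen soaks for the programmed
time; a drain valve at the container base empties it into a waste bottle, and
the cycle repeats. A protocol ("routine") is an ordered list of steps, each a
target ethanol fraction and a soak duration — e.g. the graded ethanol series
used to dehydrate and rehydrate plant tissue around propidium-iodide
staining.

The package re-implements the device's control stack hardware-agnostically:
the protocol store, pump calibration and dosing arithmetic, the schedule
compiler and run-time engine, a simulated backend, and the staining-quality
metric used to compare automated against manual processing.

# Time-based dosing

The device has no flow sensors; dosing is open loop. A calibration session
runs a pump for fixed intervals and records dispensed volumes. The default
estimator is the mean of per-measurement ratios,

$$\hat Q = \frac1n \sum_i \frac{V_i}{t_i},$$

with the sample SD of those ratios as the dispersion summary — exactly the
computation a bench calibration performs. A through-origin least-squares
slope (`method = "regression"`) is offered as an alternative; it weights long
intervals more heavily, which is statistically attractive but is not what the
bench procedure reports, so it is not the default. A volume $V$ is then
delivered by running the pump for $t = V s/\hat Q$ seconds, where $s$ is a
dimensionless delivered-volume scale factor (default 1) kept for adapting the
software to a different pump model.

Pump times are real-valued throughout planning; quantization to the
controller tick (default 0.1 s) happens once, at schedule compilation, and
the residual volume error per step is recorded in the schedule summary. At
1.1 mL/s a tick is 0.11 mL, i.e. ≤ 0.05% of a 250 mL exchange.

# Two-stock blending

A target fraction $c_t$ between stock concentrations is blended from exactly
the two adjacent stocks bracketing it:

$$v_{hi} = V\,\frac{c_t - c_{lo}}{c_{hi} - c_{lo}}, \qquad v_{lo} = V - v_{hi},$$

and an exact stock match (within $10^{-9}$) uses that stock alone. With three
stocks the blending problem is underdetermined; the bracketing-pair rule was
chosen because it minimizes consumption of absolute ethanol across a graded
series and mirrors how one would mix by hand. The rule is exposed as a
`strategy` argument so other policies can be added without touching the
scheduler. Mixing is treated as volume-additive: ethanol/water mixing in fact
loses ~3% of volume at mid fractions, but the series concentrations are
nominal labels and the device has no densitometry, so an excess-volume
correction would add parameters without a measurable reference. The tests
check the closed form against a brute-force grid search over all stock-pair
volume splits (0.1 mL grid) across a 1% target grid.

# Schedule compilation

Each step compiles to the cycle *dose → gravity fill → soak → drain*:

* pumps dose sequentially, never in parallel — a single shared time base
  makes delivered volumes independent of relay switching order (the device
  only runs pumps simultaneously in its Flush utility);
* the top valve stays open for `exchange_volume / transfer_flow_rate` plus a
  valve-actuation latency;
* the drain valve opens for a fixed `drain_time` after every soak.

By default the premix for step $k+1$ is dosed *during* step $k$'s soak
("prefetch"), so the tissue container refills immediately after draining and
the specimen is exposed to air only for the drain/refill transition (about a
minute at default settings). Whether the original firmware premixes during
the soak or strictly serially is not observable from the outside; both modes
are provided (`prefetch = FALSE` gives the serial order), and the compiler
warns when a step is too short for its successor's dose to be ready in time,
in which case the refill is delayed rather than mis-dosed.

The gravity transfer rate (default 10 mL/s), drain rate (10 mL/s), drain
time (30 s) and valve latency (2 s) are configuration values, not measured
constants: they size the transition window but do not affect dose volumes or
concentrations. The schedule reports both the step count and the summed soak
time; a 20-step, 30-minute routine totals 10 h of soak, while the full
built-in PI workflow (24 steps) totals 12 h — both figures are reported
rather than reconciled because wall time additionally includes dosing,
transfer and drain overheads.

# The virtual device

The simulator tracks volume *and ethanol mass* per compartment (stocks,
premix, tissue, waste, plus an overflow "spill" bucket), so both balances are
exact by construction. Integration is event-driven: within a horizon where
actuator states do not change, liquid moves through the bucket brigade
stocks → premix → tissue → waste in sequential clamped transfers, which is
exact whenever no container is being filled and emptied at the same time —
true for every phase of a scheduled run. The one exception is the Flush
utility (all pumps and both valves on simultaneously); there the simulator
substeps at the controller tick, keeping mass balance exact and limiting
within-substep concentration error to first order. No ODE solver is
involved.

Modeling choices, made once:

* **Perfect instantaneous mixing** in the premix container — no stirrer is
  modeled, and the gravity pour itself mixes; this is the only mixing model.
* **Complete drain** (`residual_fraction = 0` by default): the bottom valve
  empties the container; a residual-fraction parameter exists for
  sensitivity checks.
* **Finite stocks** (default 1000 mL each): a long routine can run a
  reservoir dry, as the real device would, silently but for a logged warning
  event. `required_stock_volumes()` sums a compiled schedule's per-stock
  consumption so runs can be provisioned — the 14-step dehydration series
  needs ~1350 mL of the 70% stock, more than the default load, exactly as a
  bench worker would discover when filling bottles.
* **Noise**: each time a pump switches on, its realized rate is drawn from a
  Gaussian around its nominal rate (SD per pump, default 0) from a private
  RNG stream, so equal seeds and command sequences reproduce identical runs
  regardless of the caller's RNG state.
* **Faults**: components can be injected `dead` (commands ignored, self-test
  fails) or `degraded` (rate multiplier). Container overflow routes the
  excess to the spill bucket and raises a fault event — never silent
  clipping.

The run-time engine halts on any actuation failure or device fault into the
safe state — pumps off, both valves closed — which keeps the tissue submerged
in whatever liquid is present. Pause does the same, freezes the schedule
clock, and on resume shifts all remaining actions by the pause duration, so
an interrupted dose still delivers its remaining volume. Because the library
is non-interactive, keypad-style pause/abort is expressed as timed command
injection into `run_schedule()`.

# Staining QC

Staining quality is scored on a 1-D intensity profile sampled along a line
crossing the stained tissue: the signal-to-noise ratio is the mean intensity
of the stained cell wall divided by the background intensity. The profile
itself does not label which samples are "wall" and which are "background", so
the estimator makes that segmentation explicit and overridable:

* background = mean of all samples at or below the 25th intensity percentile
  (`background_quantile`);
* signal = mean of interior local maxima exceeding
  `background_mean × min_prominence_ratio` (default 3);
* `snr = signal_mean / background_mean`, exactly; if no peak clears the
  threshold the global maximum is used and the result is flagged
  low-confidence.

Both settings are reported in the result. Background is taken from the same
profile as the signal (a per-profile convention, flagged in the output).
Welch's unequal-variance t-test was chosen for the two-group comparison: with
n = 3 per group either pooled or Welch is defensible, and Welch is the safer
default when variances are not known to match.

The synthetic generator emulates such a profile as a flat baseline plus
evenly spaced Gaussian peaks (defaults: 512 samples, 6 peaks of width 6
samples) with truncated-at-zero Gaussian noise; a "noise level" of 5% means
`noise_sd = 0.05 × background`. It records the true peak/background ratio as
ground truth. What it does *not* emulate — uneven illumination, Poisson
photon statistics, variable wall spacing and thickness, out-of-focus haze —
bounds what the recovery tests show: they validate the estimator against its
own generative model, not against real confocal data. On this model the
estimator recovers ratios 5–80 within 10% at noise levels up to 10%, with a
known upward bias (selecting the lowest intensity quartile underestimates
the background mean under noise) that grows with the noise level.

# Problem sizes and determinism

The test suite and acceptance script run entirely on synthetic inputs
generated at run time: calibration sessions of 24–240 measurements, the two
built-in PI routines (14 and 10 steps), random actuation bursts of ~50
commands, 11-seed SNR recovery grids, and 2000-replicate null calibration of
the Welch test — sizes chosen so the whole suite completes in well under a
minute while keeping Monte-Carlo acceptance bands narrow. Every stochastic
component takes an explicit seed; simulated runs of the full 12-hour PI
workflow execute in a fraction of a second because soak intervals advance in
a single event step.

# Known limitations

* Open-loop dosing means calibration bias propagates directly to delivered
  volumes (visible in the simulator when the device's true rate differs from
  the calibration estimate); there is no closed-loop sensing, matching the
  hardware.
* Tubing dead volume, evaporation during soaks, and thermal effects are not
  modeled.
* The blending model is volume-additive and ethanol/water-specific in
  interpretation only; other miscible solvent pairs work unchanged but share
  the same approximation.
* The QC module handles 1-D profiles; extracting a profile from a 2-D image
  is left to the imaging software that exported it.
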