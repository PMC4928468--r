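---
title: "Fitting individual sIPSC events with a gephyrin-dependent kinetic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting individual sIPSC events with a gephyrin-dependent kinetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sipscfit)
```

## The model

`sipscfit` fits single spontaneous inhibitory postsynaptic currents
(sIPSCs) recorded under voltage clamp, one event at a time, with a
kinetic model of the transsynaptic signaling behind the event.  The
shipped scheme couples four quantities, all in arbitrary units unless
noted: the gephyrin scaffold level `GEPH` (held constant within one
event), the neuroligin-2/neurexin adhesion level `NLG2` with turnover
rate `φ` (1/ms), the synaptic-cleft transmitter level `N` with clearance
rate `α_b` (1/ms), and the postsynaptic receptor pool `Ry` maintained by
insertion and removal rates `h`, `h1` (1/ms).  Synaptic activation is a
conductance pulse `g(t) = w (e^{-t/τ_d} - e^{-t/τ_r})` with rise and
decay constants `τ_r < τ_d` (ms).  The current is
`I = c1 · N · Ry · (v - e_rev)`, where `c1` carries the scaling to pA and
`(v - e_rev)` is the driving force in mV.

`NLG2` production follows Michaelis–Menten kinetics saturating at
`Nlmax = GEPH` with half-saturation `Nhalf = GEPH/2`, so its steady state
is `NLG2* = GEPH (2 - φ) / (2φ)` — positive only for `φ < 2`, which is
why parameter vectors with `φ ≥ 2` are excluded.  The receptor pool
settles at `Ry* = (h/h1) GEPH`.

**Transmitter drive.** Within one event `NLG2` and `Ry` sit at their
steady states and only `N` is dynamic.  The transmitter balance is
driven by the *rate-normalized* conductance pulse,

```
dN/dt = β α_f NLG2 · w (e^{-t/τ_r}/τ_r - e^{-t/τ_d}/τ_d) - α_b N ,
```

a definition chosen so that the current's rise is genuinely governed by
`τ_r` (sub-millisecond to millisecond times to peak, as observed for
somatic GABAergic events) rather than by the slow integral of the pulse.
With `N(0) = 0` this gives the closed-form current evaluated by
`eval_current_analytic()`:

```
I(t) = I_FACT · S(t - t0) · (v - e_rev)
S(t) = [((1-α_b τ_d) - (1-α_b τ_r)) e^{-α_b t} + (1-α_b τ_r) e^{-t/τ_d}
        - (1-α_b τ_d) e^{-t/τ_r}] / [(1-α_b τ_d)(1-α_b τ_r)]
I_FACT = c1 (h/h1) GEPH² (2-φ)/(2φ) · β α_f w
```

`integrate_ode()` integrates the same system numerically (deSolve/LSODA
at `rtol = 1e-10`) and serves as the independent oracle: the two routes
agree to better than 1e-6 relative error across the admissible parameter
space (this is asserted in the test suite over 100 random draws).

Two structural properties follow directly and drive everything else in
the package:

* **Identifiability.** The shape `S` depends only on
  `(α_b, τ_r, τ_d, t0)`; all seven remaining parameters act through the
  scalar `I_FACT`.  Two parameter vectors with equal
  `(I_FACT, α_b, τ_r, τ_d, t0)` produce bit-identical currents, so a
  full-parameter fit is degenerate by construction and only the lumped
  amplitude is estimable from a single event.  The ensemble analyses
  (Spearman matrices over accepted fits) make this degeneracy visible as
  strong compensating correlations, e.g. `log h` moving one-for-one
  against the log of the remaining amplitude product.
* **A discrete symmetry.** Beyond the continuous amplitude degeneracy,
  the shape is *exactly* invariant under swapping the two decay rates,
  `α_b ↔ 1/τ_d`, combined with the amplitude rescaling
  `μ = (1/τ_r − α_b)/(1/τ_r − 1/τ_d)` (an algebraic identity, asserted
  to machine precision in the tests).  `(α_b, τ_d, I_FACT)` is therefore
  identifiable only up to a two-fold orbit; `canonicalize_decay()` maps
  any set to the representative with `α_b τ_d ≤ 1` (clearance slower
  than conductance decay, where `e^{-α_b t}` is the slow tail), and
  recovery experiments compare truth and estimate in this canonical
  form.
* **Scaling laws.** `I` is exactly linear in `c1`, `β`, `α_f`, `w`, `h`
  and `1/h1`, quadratic in `GEPH`, and hyperbolic in `φ` through
  `(2-φ)/(2φ)`.  These are machine-precision identities and are tested
  as such.

**A model limitation to be aware of:** the normalized drive integrates
to zero, so `S(t)` develops a shallow counter-lobe at late times (the
`e^{-α_b t}` term changes the sign of the decay tail).  For the
parameter ranges of interest the lobe lies beyond the 20%-of-peak clip
point, so the fitted window never contains it; it does mean the model
should not be extrapolated far past the clip point.  The singularities
of the closed form at `α_b τ_r = 1` and `α_b τ_d = 1` are removable;
rather than special-casing the limit we reject vectors within 1e-6 of
either singular surface, which composes naturally with the exclusion-rule
machinery and is invisible to the optimizer in practice.

The driving force uses the chloride reversal potential.
`nernst_potential()` and `solution_chloride()` compute it from solution
compositions; a 72 mM pipette / 132.5 mM bath chloride pair at 32 °C
gives −16.0 mV, the default `erev` of `clamp_context()`.

## Preprocessing

Raw sweeps are recorded as-is (inward events are negative deflections on
a holding current of tens of pA).  The pipeline:

1. **Baseline.** The holding level is anchored on the leading 5 ms of
   the sweep, the event onset is the last pre-peak sample below 3 noise
   SDs (noise estimated from first differences, which are insensitive to
   the slow event), and the mean of the 5 ms immediately before the
   onset is subtracted.
2. **Detection.** A moving window of width `max(1 ms, 20·dt)`, capped at
   5% of the sweep duration, slides over the trace; samples where the
   within-window *range* exceeds 10% of the sweep's peak magnitude mark
   change regions.  The range threshold is floored at 6 noise SDs so
   that noise alone cannot saturate detection, and regions with no
   valley below the detection level between them are merged — the range
   statistic goes quiet over the flat top of a slow event, which must
   not split one event into a rise and a decay region.  Candidate
   regions whose peak stays below 5 noise SDs are discarded, so a
   pure-noise sweep yields no events.
3. **Clipping and status.** Each event is flipped to positive magnitude
   and cut at the first post-peak sample where a smoothed copy (3-sample
   median filter followed by a moving-window mean) decays to 20% of the
   peak; the smoothing exists so that single noise excursions neither
   clip the event early nor bias the retained tail low.  An event is
   `rejected_short` when less than 5 ms survive after the peak and
   `rejected_overlap` when the smoothed decay rebounds by more than 10%
   of the peak before reaching the clip level (the rebound scan starts
   half a window past the peak, where the centered mean no longer
   straddles the rise).  All thresholds (10% detection, 20% clip, 5 ms
   minimum, 10% RMSE acceptance) are arguments with these defaults.

Preprocessing is fully deterministic.

## Configuration dialect

A fit is specified by a plain-text file with five fixed sections:
fitted parameters with initial values, bounds, dependency rules for
parameters that are *not* fitted (evaluated in declaration order;
forward references are errors), exclusion rules (boolean expressions
that reject a parameter vector, e.g. `syn[0].geph < syn[0].nhalf*syn[0].phi`,
which encodes `φ > 2`), and a warning set with *all-except* semantics
(listed parameters are exempt from boundary-outlier warnings).  The
expression grammar is deliberately tiny — names, numbers, `+ - * / ^`,
comparisons, parentheses — and `^*^` is accepted as a typographic variant
of `*`.  NEURON-style names (`syn[0].tau1`, `nc[0].weight`,
`nstim.start`) are aliases for the model's canonical parameters, so
config files written for that environment parse verbatim.  A canonical
serializer round-trips byte-identically, which the tests assert.

Because the model is addressed only through the config and a
`fit_model_*()` object (defaults + aliases + current function), swapping
the config file swaps the kinetic scheme: the same machinery fits the
built-in peak-normalized bi-exponential model (`fit_model_biexp()`),
whose conductance maximum equals its `weight` parameter.

## Fitting

The cost is the RMSE between the model-current magnitude and the
retained samples of the event; an optional `running_mean` mode smooths
the data (window equal to the detection window) before the residual.  A
fit is accepted when RMSE < 10% of the event's peak amplitude; accepted
fits with a parameter within 1% of the bound range of either bound are
flagged as boundary-pinned (such fits indicate non-identifiable or
misspecified parameters).

`praxis_minimize()` is a direction-set (principal-axis) derivative-free
local minimizer: Brent line minimization along each search direction,
with Powell's update replacing the direction of largest decrease by the
cycle displacement when the standard acceptance test holds.  Box bounds
are imposed by a logistic reparameterization of each coordinate, which
keeps the working objective smooth, guarantees feasibility, and lets
boundary minima be approached smoothly; starts are drawn uniformly in
the original (bounded) space.  The evaluation budget (default 3000 per
start, the enforceable analogue of optimizer iteration steps) is a hard
cap; a start also ends early once the RMSE falls below 1e-6 of the peak
amplitude, three decades below the acceptance threshold.  Line-search
tolerances tighten geometrically over cycles, from 1e-3 to 1e-7 in
z-space.

Multi-start seeding is `base_seed + 10000·trace_index + start_index`, so
results are independent of execution order and of the number of worker
processes; the command-line driver merges per-trace results in trace
order.  Initial vectors violating an exclusion rule are redrawn.
Everything is deterministic given `(inputs, config, seed)`.

## Synthetic data

`generate_dataset()` emulates the recordings this pipeline targets, and
its defaults are the package's study conditions: 0.05 ms sampling
(20 kHz-like) over 80 ms with a 20 ms pre-event baseline; peak
amplitudes drawn from a four-parameter pseudo-Voigt profile
(`a·[c/(1+u²) + (1-c)·e^{-u²/2}]`, `u = (x-x0)/b`) restricted to
10–100 pA, defaulting to a mode near 37 pA with width 13 pA; rise
constants uniform in 0.05–0.5 ms and decay constants in 3–20 ms
(experimentally plausible ranges for somatic GABAergic events);
clearance `α_b` uniform in 0.02–0.12/ms; turnover `φ` in 0.3–1.7;
the remaining rates in 0.5–2; white noise of 2 pA SD; a holding offset
uniform in −60…−20 pA; optional overlapping second events at a 1–20 ms
lag.  Each trace's amplitude is calibrated by solving for `c1` given the
sampled peak, leaving the kinetics untouched so identifiability tests
remain meaningful; generation is bit-reproducible from `(spec, seed)`.

What the generator does **not** emulate: 1/f and series-resistance
noise, acquisition artifacts, event trains with realistic inter-event
statistics, or dendritic (space-clamp) filtering.  Passing recovery
tests therefore demonstrates correctness of the pipeline and estimator
under idealized noise, not robustness to every feature of real
recordings.

## What recovery experiments can and cannot show

`run_recovery()` drives the full pipeline end to end against ground
truth, fitting the *identifiable* parameterization (amplitude scale,
`α_b`, `τ_r`, `τ_d`, onset) with the remaining rates pinned by
dependency rules — fitting all eleven parameters would only re-measure
the built-in degeneracy.  Truth and estimates are compared on the
canonical branch of the decay-rate orbit (`canonicalize_decay()`).  On
noiseless events the best fits reach RMSE below 0.1% of peak and recover
the identifiable set to well under 1% (median).  At 5%-of-peak noise the
amplitude factor and `τ_r` remain sharply determined (medians within
1–2%), but the two decay-shape parameters `α_b` and `τ_d` are only
weakly constrained by a single 20%-clipped event: even on the canonical
branch they trade against each other along a flat valley of the cost
surface, individual estimates scatter by tens of percent, and their
across-event medians drift below truth.  The acceptance script reports
these medians as measured; treat per-event `α_b` estimates at realistic
noise as ensemble-level, not event-level, information.

Problem sizes used by the tests and the acceptance script — 50 synthetic
events, 12 starts (noiseless) or 10 starts (noisy), 3000 evaluations per
start, 100 parameter draws for the oracle check — are the package's
standard experiment sizes, chosen to give stable medians from a single
seeded run.

## Ensemble statistics

Pooled analyses default to the best fit per trace, to avoid
over-weighting clean traces that yield many acceptable fits; trace-level
analyses can use full ensembles.  `spearman_matrix()` computes the rank
correlation structure with an |ρ| > 0.2 highlight mask and refuses
constant columns.  `group_compare()` runs the Kruskal–Wallis omnibus
test and, when it is significant at `α` (default 0.05), pairwise
comparisons by Dunn's rank-based z statistic with tie correction
(implemented in-package; the family-wise adjustment defaults to
Bonferroni and is recorded in the output) or by a Tukey-type studentized
range test on mean ranks.  Being rank-based, results are invariant under
any common strictly monotone transform.  `fit_pseudo_voigt()`
least-squares-fits the four-parameter profile to fixed-width 5 pA
histogram bins (Levenberg–Marquardt via minpack.lm) and reports the
Pearson correlation between curve and bin heights;
`time_to_peak_stats()` correlates analytic times to peak with event
amplitudes — under the generator, amplitudes are assigned independently
of kinetics, so the expected correlation is zero, the signature of
events unaffected by cable filtering.

## Known limitations

* Per-event estimates of `α_b` and `τ_d` at realistic noise are
  ensemble-level information (see above); the 20% clip, necessary to
  avoid contamination by late events, removes exactly the tail that
  would pin them.
* The late counter-lobe of the closed form restricts the model's domain
  to the pre-clip window.
* The expression grammar has no functions or conditionals by design.
* Detection is threshold-based; template-matching or deconvolution
  detectors for heavily overlapping event trains are out of scope, as
  are series-resistance compensation and cable-filter corrections.
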