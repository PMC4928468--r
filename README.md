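# sipscfit

Kinetic-model fitting of individual spontaneous inhibitory postsynaptic
currents (sIPSCs).

## What this package is for

Whole-cell voltage-clamp recordings of GABA-A-mediated spontaneous events
are usually analyzed by averaging many events and fitting the average.
Averaging throws away exactly the information that makes spontaneous
events interesting: every synapse has its own activation history, so the
subcellular variables behind each event differ from event to event.
`sipscfit` fits **each event separately** with a user-configurable kinetic
model and treats the resulting *ensemble* of acceptable parameter sets —
not a single point estimate — as the object of analysis.  It is intended
for electrophysiologists and modelers who want to connect single-event
current time courses to transsynaptic signaling parameters, and for
methodologists interested in identifiability of synaptic kinetic models.

The shipped model is a gephyrin-dependent transsynaptic scheme.  Gephyrin
(`GEPH`, assumed constant during one event) scaffolds postsynaptic GABA-A
receptors and, through the neuroligin-2/neurexin adhesion pair (`NLG2`,
turnover rate `φ`), feeds back on presynaptic function.  A conductance
pulse

    g(t) = w · (e^(−t/τ_d) − e^(−t/τ_r))

drives the synaptic-cleft transmitter balance `N(t)` (clearance rate
`α_b`), while receptors `Ry` follow insertion/removal rates `h`, `h1`:

    dN/dt    = β·α_f·NLG2·ġ(t) − α_b·N          (ġ: rate-normalized pulse)
    dNLG2/dt = Nlmax/(1 + Nhalf/NLG2) − φ·NLG2,   Nlmax = GEPH, Nhalf = GEPH/2
    dRy/dt   = h·GEPH − h1·Ry
    I(t)     = c1 · N · Ry · (v − e_rev)

With `NLG2` and `Ry` at their steady states the current has a closed form

    I(t) = I_FACT · S(t − t0; α_b, τ_r, τ_d) · (v − e_rev),
    I_FACT = c1 · (h/h1) · GEPH² · (2 − φ)/(2φ) · β · α_f · w

so the *shape* depends only on `(α_b, τ_r, τ_d, t0)` and everything else
enters through the amplitude factor `I_FACT` — the model's identifiable
combination, quadratic in `GEPH` and hyperbolic in `φ`.  A numerical ODE
integrator (`integrate_ode()`) provides an independent check of the
closed form at 1e-6 relative accuracy.

The full procedure:

1. **Preprocess** raw sweeps: baseline/holding-current removal, moving-
   window event detection (changes > 10% of the trace peak), clipping at
   20% of the peak, rejection of events shorter than 5 ms after the peak
   or overlapping a second event before the 20% decay point.
2. **Configure** the fit with a plain-text file: fitted parameters,
   initial values, bounds, dependency rules (`nhalf = geph/2`), exclusion
   rules (`geph < nhalf*phi`), and a warning set.  Swapping the config
   (e.g. to the built-in bi-exponential scheme) swaps the model with no
   code change.
3. **Fit** each event by multi-start (default 100 randomized initial
   conditions, up to 3000 objective evaluations each) bounded
   derivative-free principal-axis minimization of the RMSE; fits with
   RMSE below 10% of the event peak form the event's ensemble.
4. **Analyze** ensembles: Spearman correlation structure (|ρ| > 0.2
   highlighting) exposing parameter degeneracies, Kruskal–Wallis with
   Dunn or Tukey-on-ranks post hocs at experiment/cell/trace level,
   pseudo-Voigt fits of peak-amplitude histograms, and time-to-peak
   versus amplitude diagnostics.
5. **Simulate**: a synthetic-data generator with pseudo-Voigt-distributed
   peak amplitudes and known ground truth for recovery testing.

## Worked example

```r
library(sipscfit)

ctx <- clamp_context(v = -70, erev = -16)   # E_Cl from the Nernst equation:
nernst_potential(solution_chloride(c(NaCl = 126, KCl = 2.5, CaCl2 = 2)),
                 solution_chloride(c(KCl = 70, MgCl2 = 1)),
                 temperature_c = 32, z = -1)
#> [1] -16.03824

truth <- gephyrin_params(w = 1, tau_r = 0.2, tau_d = 8, beta = 1,
                         alpha_f = 1, alpha_b = 0.06, geph = 1.2,
                         phi = 0.8, h = 1, h1 = 1, c1 = 2, t0 = 20)
steady_states(truth)$i_fact                 # identifiable amplitude factor
#> [1] 2.16

# one synthetic sweep: event + noise on a -40 pA holding current
trace <- generate_trace(truth, ctx, noise_model(sigma = 2, offset = -40),
                        time_grid(dt = 0.05, n = 1600), seed = 42)
ev <- preprocess_trace(trace)[[1]]
ev
#> <event_trace> ?: accepted, peak 104.0 pA @ 3.70 ms, 206 samples

cfg <- parse_config(file = system.file("extdata", "gephyrin_reduced.cfg",
                                       package = "sipscfit"))
ens <- fit_trace(ev, cfg, fit_model_gephyrin(ctx),
                 n_starts = 10, max_eval = 3000, seed = 1)
ens
#> <fit_ensemble> trace NA: fitted, 10/10 start(s) accepted, best rmse_frac 0.0196
round(unlist(best_fit(ens)[c("syn[0].alphab", "syn[0].taur",
                             "syn[0].taud", "rmse_frac")]), 4)
#> syn[0].alphab   syn[0].taur   syn[0].taud     rmse_frac
#>        0.0663        0.1964        8.4816        0.0196
```

The fitted decay parameters sit close to the generating values
(`α_b = 0.06`, `τ_r = 0.2`, `τ_d = 8`); the residual RMSE equals 2% of
the event peak, well below the 10% acceptance threshold.

The same pipeline runs from the shell:

```sh
sipscfit simulate --n 50 --seed 1 --out traces/
sipscfit fit --config gephyrin_reduced.cfg --input traces/ --out fitout/ \
             --seed 1 --n-starts 100 --max-iter 3000 --workers 4
sipscfit analyze --input fitout/ --param "syn[0].alphab" --level cell
```

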