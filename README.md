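# hergmarkov

Markov modelling of hERG (Kv11.1) channel gating and its modulation by
long-chain acylcarnitines, for cardiac electrophysiologists and modellers.

Long-chain acylcarnitines (LCAC, e.g. palmitoyl-carnitine, C16-CAR) are
fatty-acid esters whose plasma concentration rises in ischaemia, diabetes
and fatty-acid oxidation disorders and falls in primary carnitine
deficiency — all pro-arrhythmic states. Applied extracellularly at
physiological micromolar concentrations, LCAC increase the amplitude of the
rapid delayed rectifier current I_Kr carried by hERG and accelerate its
deactivation. This package implements the computational side of that
observation end to end:

- **Five-state Markov gating chain** `C1 ⇌ C2 ⇌ C3 ⇌ O ⇌ I` with
  voltage-dependent transition rates `k(V) = a·exp(b·(V + v0))` (1/ms), and
  the two published parameter sets: control saline (`pss_rates()`) and 3 µM
  palmitoyl-carnitine (`c16car_rates()`). Occupancies evolve by the master
  equation `dp/dt = Q(V)·p`; the open state carries
  `I_Kr = g_Kr·√(K_o/5.4)·p_O·(V − E_K)`.
- **Voltage-clamp simulator** for the standard hERG protocol families
  (current–voltage steps with tails at −55 mV, repeated single steps to
  −10 mV, two-pulse availability), with the tail-peak and end-pulse
  measurements used in patch-clamp analysis.
- **Analysis fits**: two-exponential deactivation
  `I(t) = A0 + A1·e^(−t/τ1) + A2·e^(−t/τ2)` (τ1 slow), Boltzmann
  activation/availability `I/Imax = 1 / (1 + exp(±(V½ − V)/s))`, and
  Nelder–Mead simplex estimation of Markov rate constants from current
  traces.
- **Ventricular action potential**: the Ten Tusscher–Panfilov (2006) human
  endocardial cell model with its Hodgkin–Huxley I_Kr replaced by the
  Markov chain, paced to a limit cycle, with APD90/APD50 metrics.
- **Synthetic data**: reproducible noisy tails, Boltzmann datasets and
  per-cell cohorts (mean ± SEM tables) so every analysis stage can be
  validated without recordings.

## Worked example

```r
library(hergmarkov)

# deactivating tail at -55 mV after a 5 s step to -10 mV, both conditions
for (params in list(pss_rates(), c16car_rates())) {
  fam <- simulate_family(build_single_step_family(dt = 1), params, dt_out = 1)
  tr  <- fam$traces[[1]]
  pk  <- measure_tail_peak(tr, 3)
  fit <- fit_biexp(tr, window = c(pk$time, max(tr$time)))
  cat(params$condition, ": tau_slow =", round(coef(fit)[["tau1"]]), "ms\n")
}
#> PSS : tau_slow = 2474 ms
#> C16CAR : tau_slow = 1258 ms

# paced endocardial cell, 50 beats at 1 Hz
ap_pss <- simulate_paced(pss_rates(),    pacing_spec(beats = 50))
ap_c16 <- simulate_paced(c16car_rates(), pacing_spec(beats = 50))
cat("APD90:", round(ap_pss$beats$apd90[50], 1), "vs",
    round(ap_c16$beats$apd90[50], 1), "ms\n")
#> APD90: 344.1 vs 209.2 ms
```

The tail fit shows the acylcarnitine condition deactivating roughly twice
as fast at −55 mV; in the paced cell the same rate change shortens the
action potential by ~135 ms — the pronounced AP shortening predicted for
LCAC accumulation. The methods vignette
(`vignettes/herg-markov-modelling.Rmd`) documents the model, its numerical
backends and the design choices.

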