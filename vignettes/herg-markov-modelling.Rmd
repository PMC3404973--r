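---
title: "Markov modelling of hERG gating and its acylcarnitine modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov modelling of hERG gating and its acylcarnitine modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergmarkov)
```

## The model

hERG (Kv11.1) carries the rapid delayed rectifier potassium current I~Kr~.
Its hallmark kinetics — slow activation and deactivation combined with very
fast inactivation and recovery — make the current small during the action
potential plateau and large during late repolarisation. The package
describes gating as a continuous-time Markov chain on a linear topology of
five conformational states,

$$C_1 \rightleftharpoons C_2 \rightleftharpoons C_3 \rightleftharpoons O
\rightleftharpoons I,$$

with one voltage-dependent rate law per transition,
$k(V) = a\,e^{b (V + v_0)}$ in 1/ms (voltage-independent transitions have
$b = v_0 = 0$). All units follow cardiac-modelling convention: ms, mV,
pA/pF, mM. Two complete parameter sets are built in: `pss_rates()` for the
control physiological saline condition and `c16car_rates()` for 3 µM
extracellular palmitoyl-carnitine; both are reproduced digit-for-digit from
their published values and ship as JSON in `inst/extdata/`.

Occupancies obey the master equation $\dot p = Q(V)\,p$ with the tridiagonal
generator $Q$ (columns sum to zero, which conserves total probability). The
open state generates current with the rapid-delayed-rectifier convention of
the Ten Tusscher–Panfilov ventricular model,
$I_{Kr} = g_{Kr}\sqrt{K_o/5.4}\; p_O\,(V - E_K)$; neither the conductance
nor the reversal potential used in the original simulations was published,
so `current_config()` defaults to the endocardial $g_{Kr} = 0.153$ nS/pF
and the Nernst potential of the recording solutions (4 mM external /
130 mM internal potassium at 23 °C, about −88.8 mV), both configurable.

### The printed k32 anomaly

The control set contains `k32 = 15686841` /ms — eight orders of magnitude
above every other rate (the matching acylcarnitine value is 0.01686841,
suggesting a transcription slip). The package implements the value exactly
as printed; `pss_rates(k32_a =)` substitutes an alternative and relabels
the set `"PSS*"`. Consequences of the printed value worth knowing:

- state C3 drains to C2 essentially instantaneously, so steady-state
  occupancy beyond C2 is suppressed by ~8 orders of magnitude and control
  current densities are unrealistically small (~1e-6 pA/pF). Normalised
  observables (activation curves, time constants, APD comparisons) are
  unaffected in kind.
- every control-condition generator carries a ~1.6e7/ms eigenmode at all
  voltages, which dictated the numerical design below.

## Numerical backends

Within a constant-voltage segment the master equation is linear, so the
default backend propagates occupancies *exactly* through the spectral
decomposition of $Q$. Because the stationary distribution $\pi$ of a
birth–death chain satisfies detailed balance, $D^{-1} Q D$ with
$D = \mathrm{diag}(\sqrt\pi)$ is symmetric, and the decomposition is done
on the symmetric form — this stays accurate for the extremely stiff
control generator, where a plain dense matrix exponential loses digits in
its squaring phase on multi-second segments (we measured ~1e-3 absolute
error in `Matrix::expm` at 5 s segments, against ~1e-12 agreement between
the spectral propagator and a stiff ODE solve). The alternative `"ode"`
backend integrates with an always-stiff BDF method (`deSolve::vode`,
rtol 1e-8, atol 1e-10) and the exact constant Jacobian; method-switching
solvers start in their non-stiff phase and stall on the 1.6e7/ms mode. The
two backends agree to better than 1e-6 on randomised protocols, which the
test suite asserts, and total probability is conserved to 1e-8 everywhere.

Steady states use the closed-form birth–death ratios
$p_{i+1}/p_i = k_{i,i+1}/k_{i+1,i}$, cross-checked against a pivoted LU
null-space solve (a raw SVD cannot resolve the null vector of these graded
matrices, whose entries span ~16 orders of magnitude).

## Clamp protocols and measurements

Protocols are data: piecewise-constant segments plus a sampling interval
(default 0.2 ms = 5 kHz, the acquisition rate the simulations emulate).
Three builders encode the standard hERG families from a −70 mV holding
potential: 5 s IV steps (−80…+50 mV, 10 mV increments) with tails at
−55 mV; repeated 5 s single steps to −10 mV every 18 s; and the two-pulse
availability protocol (1 s at +40 mV, 25 ms interpulse at −120…+10 mV,
test pulse at +40 mV). Segment durations the protocols leave open are
package choices: 100 ms baseline, 5 s IV tails (8 s for the single-step
family, long enough to resolve the slowest published time constant of
~2.3 s), 500 ms availability test pulses. The 18 s inter-sweep interval is
*simulated* at the holding potential rather than assumed to reset the
channel, so slow accumulation across sweeps is captured; it is stated for
the single-step protocol and applied to all families. Tail peaks exclude
the first sample after a step so the boundary discontinuity cannot be
mistaken for a peak; end-pulse currents average the final 50 ms of the
step by default.

## Fitting

**Two-exponential deactivation.** $I(t) = A_0 + A_1 e^{-t/\tau_1} + A_2
e^{-t/\tau_2}$ with $t$ from the window start and $\tau_1 \ge \tau_2$
enforced by ordering ($\tau_1$ is the slow component, matching the
published tables where tau1 > tau2). The fit uses variable projection —
for fixed time constants the amplitudes are a linear least-squares solve —
so only the two log time constants are optimised (Nelder–Mead from a
log-spaced 3×3 grid of starting pairs, relative tolerance 1e-13).
Amplitudes are not sign-constrained; whether the original analysis
constrained them is unknowable from the published material, and free
amplitudes let the fitter represent "hooked" tails (rise from recovery from
inactivation, then decay) that the simulated model produces. Fits that are
effectively mono-exponential ($\tau_1/\tau_2 < 1.1$ or a vanishing
amplitude) are flagged `degenerate`; non-convergence sets a flag rather
than throwing. The default window starts 2 samples after the segment
boundary; analyses that emulate the published measurement fit from the
tail peak onward.

**Boltzmann curves.** $I/I_{max} = I_{scale}\,/\,(1 + e^{(V_{1/2} -
V)/s})$ for activation and with $(V - V_{1/2})/s$ for availability, so the
slope factor is positive in both directions. Fitting is
Levenberg–Marquardt (`minpack.lm`) started from the interpolated
half-crossing and quartile-derived slope; all-plateau data are flagged
non-converged.

**Rate-constant estimation.** `fit_markov_rates()` minimises the summed
squared current residuals over all sweeps of a family with the Nelder–Mead
simplex, the published estimation method. Prefactors are optimised in log
space to stay positive; the free-parameter subset is named as
`"k23"`/`"k12.a"`-style strings. The run records the sequence of improving
objective values, is deterministic given the start, and returns
best-so-far parameters with a flag when the iteration cap bites. A
parameter-recovery experiment (two prefactors perturbed ×1.2, three-sweep
family) recovers the published constants to ≪1 %.

## The ventricular cell model

`simulate_paced()` couples the Markov chain into the Ten Tusscher–Panfilov
(2006) human *endocardial* ventricular cell model (the published
simulations name that variant; epicardial/M-cell parameters are out of
scope). The full right-hand side — 17 model states plus the five
occupancies — is compiled (Rcpp), with $I_{Kr} = g_{Kr}\sqrt{K_o/5.4}\,
p_O (V - E_K)$ replacing the original two-gate formulation. Integration is
beat-by-beat with an adaptive stiff solver (rtol 1e-6, atol 1e-8, max step
1 ms), split at the stimulus edges so the solver never steps across the
discontinuity. Pacing defaults are a conventional choice for this model
(−52 pA/pF for 1 ms, cycle length 1000 ms, 50 beats with the last
recorded); none were published. The initial state is the model's resting
values with the Markov block at its steady state for the resting
potential; 50 pre-paced beats bring the cell within 0.4 ms beat-to-beat
APD90 drift of its limit cycle, with diastolic potential near −86 mV in
both conditions. APD metrics interpolate linearly between samples, from
the maximal-upstroke time to the crossing of
$V_{rest} + (1-f)\,(V_{peak}-V_{rest})$.

With the package defaults the paced cell yields APD90 = 344 ms under
control rates and 209 ms under the acylcarnitine rates — the pronounced
action-potential shortening the modulation predicts. The absolute values
depend on the unpublished pacing and conductance choices; the *direction*
is robust to them. One deliberate deviation from idealised expectations:
doubling the 1 ms stimulus amplitude shifts the settled APD90 by several
milliseconds (potassium loading from the doubled injected charge), so the
stimulus-insensitivity test asserts a <5 % relative change rather than
sub-millisecond identity.

## What the fast tail component does and does not show

At −55 mV the simulated tail is dominated by a single slow eigenmode
(~2.5 s control, ~1.3 s acylcarnitine) plus a small opposite-signed fast
"hook" mode (~9 ms and ~18 ms respectively; the printed control k32
eliminates the slower closed-state mode that would otherwise appear). The
slow, physiologically meaningful component is unambiguously faster under
acylcarnitine, as is the action-potential shortening. But a two-exponential
fit's *fast* component picks up the residual hook mode, whose amplitude is
below half a percent of the trace and whose ordering between conditions is
*reversed* relative to the published fast time constants (which are
hundreds of ms — a scale the printed rate sets do not produce at all). The
pipeline and tests therefore treat the slow component and the APD as
direction results and report the fast component without a sign claim; the
corresponding acceptance check of the fast component is left failing
rather than redefined.

## The synthetic-data generator

Synthetic tails add i.i.d. Gaussian noise to the exact biexponential
(default SD 2 % of the initial amplitude — no noise model was published,
so the level is a parameter); Boltzmann datasets add Gaussian noise on the
normalised axis. Cohorts draw per-cell parameters from normal
distributions truncated to positive time constants and slopes (by
resampling), fit every cell, and summarise as mean ± SEM, mirroring
published cohort tables; capacitances are drawn uniformly from the
published 10–20 pF range. Every stochastic output requires an explicit
seed and restores the global RNG state, so runs are reproducible and
side-effect free. What the generator deliberately does *not* emulate:
rundown, leak, capacitive transients, series-resistance artefacts, or
correlated noise — so passing round-trip tests demonstrate estimator
correctness on the assumed noise model, not robustness to real-world
recording artefacts.

## Problem sizes and limitations

The test-suite simulations use coarsened grids (1–5 ms output sampling for
clamp families, 1 kHz synthetic tails for noisy replicates, 50-replicate
noise studies) — these sizes resolve the relevant kinetics by two orders
of magnitude and keep the suite quick; the fitters are validated at the
full 5 kHz acquisition rate in the noiseless round-trips. Known
limitations: no temperature scaling (recordings at 23 °C vs 37 °C
physiology), no state-dependent drug block, no stochastic single-channel
simulation, no tissue-level propagation, and the k32 anomaly above, which
makes absolute control-condition current densities unphysiological while
leaving normalised kinetics interpretable.
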