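---
title: "Modelling Nav1.6 gating, CaMKII modulation, and pacemaker excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Nav1.6 gating, CaMKII modulation, and pacemaker excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nav16sim)
```

# The gating model

Sodium currents are generated by a 13-state Markov scheme of the kind used
for resurgent-current-capable Nav channels: five closed states `C1..C5`
(four independent voltage sensors give the 4α, 3α, 2α, α forward and β, 2β,
3β, 4β backward multiplicities), an open state `O` reached from `C5` via the
voltage-independent rates γ (opening) and δ (closing), an open-blocked state
`OB`, and a parallel inactivated tier `I1..I6` lying under `C1..C5` and `O`.
Occupancy evolves as `dp/dt = p Q(V)` with

* `alpha(V) = alpha0 * exp( V / k_alpha)`, `beta(V) = beta0 * exp(-V / k_beta)`
  on the closed tier (defaults `k_alpha = k_beta = 20` mV),
* vertical inactivation `Cn -> In` at `Con * alfac^(n-1)` and recovery
  `In -> Cn` at `Coff * btfac^(n-1)` with the allosteric scalings
  `alfac = (Oon/Con)^(1/4)` and `btfac = (Ooff/Coff)^(1/4)`,
* open-state inactivation `O <-> I6` at `Oon` / `Ooff`,
* an inactivated tier that mirrors the closed tier with independent base
  rates `alpha_i`, `beta_i` (scaled by `alfac` / `btfac`, same
  multiplicities) and `I5 <-> I6` via γ / δ.

Two modelling points deserve emphasis.

**Thermodynamic structure.** The quarter-power scalings make the
`C5–O–I6–I5` rectangle satisfy detailed balance identically, and the
reported allosteric factor `a = alfac/btfac = (Oon*Coff/(Ooff*Con))^(1/4)`
is recomputed whenever its inputs change (`update_rates()`), never set by
hand. The four `C/I` rectangles balance exactly when
`alpha * beta_i = alpha_i * beta`, which holds for the wild-type condition.
The mutant and CaMKII-inhibited conditions deliberately break that identity:
giving the inactivated tier its own base rates is how the voltage dependence
of activation and inactivation is partially uncoupled, at the cost of
microscopic reversibility on the closed/inactivated rectangles. The test
suite checks the balanced cases and the always-balanced open-state loop.

**Open-channel block is disabled.** Every shipped condition has the block
entry rate `epsilon = 0`, so the `OB` column of the generator is empty, the
state is unreachable, and no resurgent current is produced. The machinery is
retained (`zeta0`, `k_zeta`) for users who want to study block, but none of
the analyses here depend on it.

## Shipped conditions

`nav_preset()` provides six parameterisations: `WT`, the epilepsy-associated
variants `R639C` and `R850Q`, and each with CaMKII inhibited (`+CN21`).
They differ from wild type in a conductance multiplier (`density_scale`) and
a small set of rate constants; for example CaMKII inhibition of wild type
reduces density to 0.300x, slows activation (`alpha0` 92 vs 150 /ms), and
speeds open-state inactivation (`Oon` 1.3 vs 0.75 /ms). The table ships as
plain JSON (`extdata/nav16_conditions.json`) in the same format
`read_conditions_json()` accepts for user-defined conditions; fields a
condition does not list keep the wild-type defaults.

Because the CaMKII-inhibited wild-type condition changes kinetics as well as
density, its simulated peak current at the 0 mV step is about 0.95 x 0.300
of the wild-type peak, not exactly 0.300; only a pure `density_scale` change
scales every sample exactly (the acceptance tests distinguish the two).

## Numerics

Within a constant-voltage segment the propagator is the matrix exponential
`P = expm(Q dt)` (computed in compiled code), so clamp-protocol integration
is unconditionally stable and conserves total occupancy to machine
precision; refining `dt` (default 0.025 ms) changes only the sampling, not
the trajectory. Stationary occupancies solve `p Q = 0` with the
normalisation row appended, after pruning states with no inbound edge (the
blocked state when `epsilon = 0`); a rank check rejects schemes whose
stationary distribution is not unique. The test suite cross-checks the
matrix-exponential path against an independent adaptive ODE solver and
against closed-form limits (a closed-tier-only reduction equilibrates to a
binomial distribution over activated voltage sensors).

# Voltage-clamp protocols and analysis

Three protocols reproduce standard whole-cell characterisation: 50 ms
depolarising steps from -80 to +60 mV (5 mV increments) from holding -100 mV
(or -80 mV for the CaMKII-comparison configuration); 500 ms prepulses from
-130 to +40 mV followed by a 20 ms, 0 mV test pulse for steady-state
inactivation; and a paired-pulse recovery protocol with -80 mV gaps
(log-spaced 0.5-100 ms by default — the gap schedule is configurable since
recording protocols vary). Simulated sweeps are artifact-free: no leak,
capacitive transient, or series-resistance error; those belong to the
synthetic-recording generator.

Measurements follow the conventions of whole-cell analysis software:

* peak transient current is the signed extremum inside the step, excluding
  the first 0.05 ms after the edge (the instantaneous ohmic jump); an
  optional window average centred on the extremum (`avg_ms`, used by the
  `analyze_*` wrappers at 0.2 ms) suppresses the upward bias that
  extremum-picking has on noisy traces;
* persistent current is the mean over the final 5.0 ms of the step;
* conductance is `G = I / (V - V_rev)` with `V_rev` interpolated from the
  zero crossing of the ascending I-V limb, or extrapolated from its
  quasi-ohmic top when the protocol stops short of reversal (steps end at
  +60 mV while `E_Na` is +68 mV); points within 10 mV of `V_rev` are
  excluded from the conductance transform because the vanishing driving
  force only amplifies noise;
* activation and availability curves are fitted with
  `amplitude / (1 + exp((V50 - V)/k))` by bounded Levenberg–Marquardt least
  squares. The ascending (activation) branch uses `k > 0`; availability
  falls with depolarisation and is encoded with `k < 0` — `|k|` is the slope
  factor under either sign convention. Start values come from the
  interpolated half-maximum crossing; the normalised fit evaluates to
  exactly 0.5 at its own `V50`;
* transient decay is fitted 1.0 ms into the step with a biexponential plus
  offset, components ordered so `tau_fast <= tau_slow`; genuinely
  mono-exponential decays collapse onto a single component (the other
  amplitude returns 0) rather than failing;
* recovery fractions (test peak / conditioning peak) are fitted with
  `offset + amplitude * (1 - exp(-t/tau))`.

Condition comparisons use `percent_change()` —
`100 * (|reference| - |test|) / |reference|`, positive for reductions,
with report rounding half away from zero — and `midpoint_shift()`
(`V50_a - V50_b`, positive meaning `a` is depolarised relative to `b`).

# Synthetic whole-cell recordings

`generate_cell()` and `generate_cohort()` emulate the content of a
whole-cell recording so the analysis chain can be validated against known
ground truth: the Markov channel scaled by a per-cell maximal conductance,
an optional linear leak `g_leak (V - E_leak)`, and additive i.i.d. Gaussian
noise. Per-cell capacitance and conductance are drawn lognormal (medians 12
pF and 90 nS — typical magnitudes for small transfected cells with large
expressed currents; the spread parameters are conveniences, exposed in the
arguments). Every output records its seed, and cohorts are pure functions of
(arguments, seed): same seed, byte-identical files.

What the generator does *not* emulate: series-resistance voltage errors,
capacitive transients, leak-subtraction residues, or line noise. Recovery of
ground-truth parameters from these recordings therefore demonstrates
correctness of the analysis chain under idealised conditions, not robustness
to uncompensated recording artifacts in real data.

# The pacemaker neuron

Excitability consequences are explored in a single-compartment,
Purkinje-style spontaneously firing neuron:
`C dV/dt = -(I_Na + I_K + I_leak [+ I_h]) + I_stim`. The sodium term is a
mixture of Markov components — heterozygous expression of a mutant allele is
the composition `c(WT = 0.5, MUT = 0.5)`, and a CaMKII-inhibited neuron
switches every component to its `+CN21` parameter set. Each component
contributes `fraction * density_scale * gna` of open-channel conductance.

The non-sodium complement is deliberately minimal: a fast Kv3-like delayed
rectifier (n⁴, half-activation -24 mV, slope 15.4 mV, bell-shaped time
constant of a few ms peaking near -50 mV), an ohmic leak, and an optional
h-current (off by default). A BK-type current is not included because a
credible BK model requires intracellular calcium dynamics, which are outside
this package's scope. Defaults (mS/cm²): `gna = 16`, `gk = 35`,
`gl = 0.30`, `E_Na = +68`, `E_K = -88`, `E_leak = -61`, `cm = 1` µF/cm².

The complement was calibrated once, then frozen, against three structural
requirements: (i) the 100% wild-type neuron is a stable spontaneous
pacemaker in the tens of Hz (it fires near 49 Hz under the defaults);
(ii) firing frequency is monotone in sodium drive over the physiological
density range — an early, weaker rectifier (gk ≈ 10) put gain-of-function
compositions into depolarisation block near -32 mV, an artifact a
Purkinje-realistic Kv3 density removes; and (iii) pacemaking is driven by
the subthreshold sodium window current rather than by leak alone, with the
pacemaking boundary just below the wild-type window drive. The third
requirement is what lets conditions separate the way reduced-and-right-
shifted channels should: the heterozygous R850Q+CN21 composition carries
roughly 0.7x the wild-type steady window conductance and falls silent, while
the heterozygous R639C+CN21 composition carries roughly 1.6x and keeps
firing. The relative spontaneous-rate changes between genotypes were
measured only after the complement was frozen.

Numerically, the membrane integrator (compiled) uses backward Euler for each
occupancy vector — A-stable, exactly conservative, positivity-preserving, so
stiff gating rates at spike peaks cannot destabilise it — with Rush–Larsen
updates for the HH gates and exponential Euler for the voltage, at a fixed
`dt = 0.0025` ms. Halving the step changes the spontaneous rate by under
2% (tested). Spikes are upward crossings of -20 mV with a 1 ms lockout;
detection counts are insensitive to thresholds between -20 and 0 mV on
healthy trains. Spontaneous runs discard a 1000 ms settle period and count
spikes in a 2000 ms window; evoked runs inject 1000 ms current steps after a
settle period, one integration per amplitude.

# Problem sizes and run times

All validation runs on this package's defaults: 29-sweep I-V families at
0.025 ms sampling, 18-prepulse availability families (500 ms prepulses),
12-gap recovery series, 10-cell synthetic cohorts with noise at 2% of peak,
and 3 s of simulated time per neuron condition. The complete test suite
exercises every condition and protocol at those sizes in about a minute;
the acceptance script's from-scratch recomputation takes well under a
minute.

# Known limitations

* The auxiliary conductance complement is a minimal pacemaker, not a full
  Purkinje model; absolute firing rates and evoked gain are meaningful only
  relative to each other across channel conditions.
* With `epsilon = 0` there is no resurgent current, so firing does not probe
  block-dependent repetitive-firing mechanisms.
* The inactivated tier keeps the allosteric `alfac`/`btfac` scaling on its
  horizontal rates; with independent `alpha_i`/`beta_i` this is one of
  several defensible placements of the activation/inactivation uncoupling,
  and sensitivity to the alternative (dropping the scaling) has not been
  characterised.
* Condition parameter sets express relative, condition-level changes in
  channel behaviour; they are not fits to any specific recorded cell, and
  simulated absolute midpoints/time constants differ from typical
  experimental values by several mV/ms while preserving the relative
  orderings the package is built to study.
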