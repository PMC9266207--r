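# nav16sim

Kinetic modelling and whole-cell analysis toolkit for the voltage-gated
sodium channel Nav1.6 (*SCN8A*) and its modulation by the kinase CaMKII.

Gain-of-function Nav1.6 variants such as R639C and R850Q increase sodium
current and shift activation to hyperpolarised potentials, driving neuronal
hyperexcitability; acute CaMKII inhibition has the opposite, loss-of-function
signature. This package lets computational and experimental
electrophysiologists simulate those effects end to end — from channel gating,
through voltage-clamp characterisation, to spontaneous and evoked firing of
a pacemaking neuron with heterozygous mutant channel expression — and
provides the standard analysis chain to quantify them.

## What is inside

* **13-state Markov gating model** — closed states C1–C5 (rates 4α…α / β…4β,
  α(V) = α₀·e^(V/k_α), β(V) = β₀·e^(−V/k_β)), open state O (C5⇌O via γ/δ),
  open-blocked state OB (disabled: its entry rate ε = 0 in every shipped
  condition, eliminating resurgent current), and an inactivated tier I1–I6
  with allosteric scalings alfac = (O_on/C_on)^¼, btfac = (O_off/C_off)^¼.
  Six built-in conditions (WT, R639C, R850Q, each ± CaMKII inhibition,
  i.e. "+CN21") ship as a plain-JSON table; user conditions use the same
  format.
* **Voltage-clamp protocols** — I–V step families (−80…+60 mV, 50 ms),
  steady-state inactivation (500 ms prepulses −130…+40 mV, 20 ms test pulse
  at 0 mV), and paired-pulse recovery from fast inactivation, all integrated
  by per-segment matrix exponentials (probability-conserving to machine
  precision).
* **Analysis chain** — G = I/(V−V_rev) conductance transform with per-cell
  reversal estimation; Boltzmann fits of activation
  (G/G_max = 1/(1+e^((V₅₀−V)/k))) and availability; biexponential decay fits
  (1 ms into the step); single-exponential recovery fits; current-density
  normalisation (pA/pF); percent-change and midpoint-shift arithmetic.
* **Synthetic recordings** — whole-cell-like sweeps with known ground truth
  (lognormal cell capacitance and conductance, optional linear leak,
  Gaussian noise, fully seeded), for validating the analysis chain.
* **Pacemaker neuron** — single-compartment spontaneously firing model;
  heterozygous expression is the composition (WT 0.5, mutant 0.5); compiled
  semi-implicit integrator; spike detection and F–I curves.

## Worked example

```r
library(nav16sim)

ss_wt  <- run_protocol(iv_protocol(-100), nav_preset("WT"),    macroscopic_params(gbar = 90))
ss_mut <- run_protocol(iv_protocol(-100), nav_preset("R639C"), macroscopic_params(gbar = 90))
iv_wt  <- analyze_iv(ss_wt)
iv_mut <- analyze_iv(ss_mut)
peak0  <- function(a) a$peaks$peak[a$peaks$command == 0]

cat(sprintf("peak increase: %d%%   activation shift: %+.2f mV\n",
            -percent_change(peak0(iv_wt), peak0(iv_mut), rounded = TRUE),
            midpoint_shift(iv_mut$activation, iv_wt$activation)))

f_wt  <- simulate_spontaneous(neuron_config(het_composition("WT")))$frequency
f_mut <- simulate_spontaneous(neuron_config(het_composition("R639C")))$frequency
cat(sprintf("spontaneous firing: WT %.1f Hz, het R639C %.1f Hz (+%.0f%%)\n",
            f_wt, f_mut, 100 * (f_mut / f_wt - 1)))
```

prints

```
peak increase: 65%   activation shift: -3.79 mV
spontaneous firing: WT 48.5 Hz, het R639C 77.5 Hz (+60%)
```

The first line is the voltage-clamp signature of the R639C variant: a ~65%
larger peak current at the 0 mV step (its conductance density is 1.72× wild
type) and a hyperpolarised activation midpoint — the channel opens earlier.
The second line is the downstream excitability consequence: a neuron with
half its Nav1.6 replaced by R639C paces ~60% faster than the all-wild-type
neuron. Switching both halves to their CaMKII-inhibited parameter sets
(`het_composition("R639C", camkii_inhibited = TRUE)`) reduces that rate,
which is the package's core use case: quantifying how much CaMKII inhibition
attenuates mutant hyperexcitability.

A command-line wrapper over the same functions is installed at
`inst/cli/nav16sim.R` (subcommands `generate`, `simulate-clamp`,
`simulate-neuron`, `analyze`, `report`).

See `vignettes/nav16-model.Rmd` for the model equations, fitting
conventions, the pacemaker's design and calibration, and known limitations.

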