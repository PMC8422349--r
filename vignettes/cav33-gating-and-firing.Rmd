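---
title: "From Cav3.3 gating parameters to thalamic firing phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Cav3.3 gating parameters to thalamic firing phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatesim)
```

## The problem

Cav3.3 (gene *CACNA1I*) is the slow member of the T-type calcium channel
family, highly expressed in thalamic reticular nucleus (TRN) neurons where it
drives low-threshold calcium spikes and rebound burst firing.  Several
heterozygous missense variants near the channel's activation gate --- I860N,
I860M, I1306T and M1425I --- act as gain-of-function changes: they shift
activation to more hyperpolarized voltages, slow activation, inactivation and
deactivation, and enlarge or left-shift the window current.  `gatesim`
provides the computational chain needed to study such variants end to end:

1. a parametric Hodgkin--Huxley-style gating model of the channel
   (`channel_current()`, `window_curve()`),
2. a voltage-clamp simulator that plays the standard protocols against the
   model and emulates whole-cell recordings (`simulate_sweeps()`),
3. the standard current-analysis pipeline (`fit_iv()`,
   `fractional_activation()`, `ssi_curve()`, `fit_exp_decay()`,
   `ap_clamp_metrics()`), and
4. a single-compartment conductance-based TRN-style neuron that converts
   gating parameters into firing phenotypes (`find_rheobase()`,
   `rebound_run()`, `classify_firing_mode()`).

## The channel model

Each variant is a `gating_params` object defining the two-gate ohmic model

$$ I = \bar g\, m^p\, h\, (V - E_{rev}), \qquad
   m_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2,act})/k_{act}}}, \qquad
   h_\infty(V) = \frac{1}{1 + e^{(V - V_{1/2,inact})/k_{inact}}} $$

with first-order gate relaxation $\dot x = (x_\infty(V) - x)/\tau_x(V)$.
Design choices, and why:

* **Gate exponent $p = 2$** ($m^2h$), the standard T-current formulation in
  conductance-based thalamic models.  It is a parameter, so $p = 1$
  reproduces simpler fits.
* **Ohmic driving force** with $E_{rev} = +120$ mV.  T-channel permeation is
  better described by a constant-field relation near the reversal potential,
  but every quantity this package reports lives between $-110$ and $0$ mV
  where the two parameterizations differ only through the fitted $\bar g$;
  the ohmic form keeps the I--V fit model (`fit_iv()`) self-consistent.
* **Tabulated $\tau(V)$** with linear interpolation and constant
  extrapolation beyond the table edges, because kinetics are measured at
  discrete test potentials.  A separate deactivation table covers the
  m-gate at hyperpolarized voltages (tail currents); it must lie strictly
  below the activation table's range and the two are merged into one m-gate
  $\tau(V)$ curve for voltage-clamp simulation.
* **Exact exponential updates.**  At fixed voltage the gate ODE has the
  closed-form solution $x \leftarrow x_\infty + (x - x_\infty)e^{-dt/\tau}$;
  `step_gates()` uses it directly, so $n$ steps of $dt/n$ equal one step of
  $dt$ to machine precision, and the voltage-clamp integration is exact for
  piecewise-constant commands whose edges fall on the step grid.

The *window current* is the steady-state open fraction
$w(V) = m_\infty^p h_\infty$: channels in the overlap of the two curves are
persistently open.  Its peak location and area are the main determinants of
excitability near rest, and `window_compare()` reports both per variant.

## The shipped parameter library

The raw recordings behind the published variant characterization are not
public, so `inst/extdata/cav33_variants.json` is a **synthetic
transcription**, built and frozen once by `scripts/calibrate_params.R`:

* The wild-type baseline takes literature-typical whole-cell Cav3.3 values
  ($V_{1/2,act} = -48$ mV, $k_{act} = 5.5$ mV, $V_{1/2,inact} = -72$ mV,
  $k_{inact} = 5$ mV, $\bar g = 20$ nS, bell-shaped $\tau_{act}$ peaking at
  22 ms near $-60$ mV, $\tau_{inact}$ of 130--420 ms).
* Variants apply the published measured midpoint shifts (activation
  $-15.5 / -8.1 / -14.5 / -13.7$ mV for I860N/I860M/I1306T/M1425I;
  inactivation $-6.6 / -5.9 / 0 / -6.8$ mV) and kinetic slowings
  (fractional inactivation at 500 ms of ~52% / ~87% for I860N / I860M
  against 95--98% for wild type; time-to-peak ratios > 3x and ~2x;
  tail-current deactivation up to ~10x slower).  Because the published
  shifts are *measured* quantities, the stored gate midpoints include the
  small measurement bias of the pipeline itself (an inverse calibration,
  iterated to a fixed point and then frozen).
* Slope factors and the voltage profile of the activation-tau scaling are
  not printed anywhere; they were chosen once so that the window-current
  geometry matches the published description (wild-type peak near $-50$ mV,
  variant peaks between $-70$ and $-60$ mV, enlarged only for I860N and
  I1306T) and the published observation that activation slows mainly at
  $-50$ / $-40$ mV.

Every record carries a provenance note; re-running the calibration script
regenerates the file bit-identically and prints the full anchor checklist.

## The voltage-clamp generator

`simulate_sweeps()` equilibrates the gates at the holding potential,
relaxes them along the command on a fine grid, and records at the protocol's
sample interval (default 10 kHz).  The standard protocols are:

* `make_iv_protocol()` --- 500-ms steps, $-90..+30$ mV in 10-mV increments
  from $-100$ mV holding (a 5-s variant for inactivation-tau fits).  The
  exact test range is not printed in the published protocols; it is inferred
  from the plotted axes and configurable.
* `make_ssi_protocol()` --- reference pulse, 3-s recovery, 5-s conditioning
  at $-110..-40$ mV in 5-mV steps, test pulse; availability is the
  post/pre peak ratio.
* `make_deactivation_protocol()` --- activation step (15 ms wild type,
  50 ms variants) then tail repolarization.
* `make_ap_train_protocol()` --- 99 action-potential-like depolarizations at
  20 Hz; the AP template (`ap_waveform()`) is a piecewise exponential from
  $-70$ to $+20$ mV with a 1-ms rise and 4-ms decay constant, truncated
  after six decay constants, since the original thalamic waveform is not
  printed.

`add_noise()` adds white Gaussian recording noise with a recorded seed.
The generator deliberately does **not** emulate leak or capacitive
artefacts, series-resistance error, seal drift or line pickup; a green test
against synthetic data therefore establishes correctness of the analysis
pipeline under ideal-recording assumptions, not robustness to every
real-world artefact.

## The analysis pipeline

* `fit_iv()` fits $I(V) = g_{max}(V - E_{rev})/(1 + e^{-(V - V_{1/2})/k})$
  by damped least squares with three deterministically jittered starts
  (Nelder--Mead and BFGS, best of six), flagging non-convergence rather
  than failing silently.
* `fractional_activation()` uses the conductance transform
  $G = I_{peak}/(V - \hat E_{rev})$, not tail currents.  When the sweep
  family is supplied it corrects each conductance for the inactivation
  accrued by the time of the peak, multiplying by
  $e^{t_{peak}/\hat\tau}$ with $\hat\tau$ from the sweep's own post-peak
  mono-exponential fit; without the correction the apparent midpoint of a
  slowly activating channel is biased depolarized by up to ~1 mV.
  Corrections are skipped for sweeps below 5% of the maximal current or
  when $\hat\tau < 2\,t_{peak}$ (an unreliable decay fit would blow the
  factor up).  The normalized curve is fit with a Boltzmann raised to the
  gate exponent $p$.
* `peak_and_ttp()` uses the raw most-negative sample on noise-free data.
  For noisy sweep sets a centered moving average of ~1.5 ms is applied
  before peak picking, because raw argmin peak detection under white noise
  carries an extreme-value selection bias that would corrupt the
  conductance curve at small currents.
* `fit_exp_decay()` / `deactivation_tau()` fit
  $A e^{-(t - t_0)/\tau} + C$; tail fits start two samples after the
  repolarization edge.  For the $m^2 h$ model the observed tail time
  constant is $\tau_m/2$; with $p = 1$ it equals $\tau_m$ exactly, which
  the tests use as a closed-form oracle.
* `ap_clamp_metrics()` reports, per AP: the persistent (pace-making)
  current over the 5 ms before onset, the charge during the waveform, and
  the charge over the following 10 ms (trapezoid, pC).

**Verified accuracy** (property tests): on random physiological parameter
sets the full pipeline recovers both midpoints within 0.5 mV and the
inactivation time constant at $V_{max}$ within 2% from noise-free data, and
is unbiased within 1 mV under 5%-of-peak recording noise.  These bounds
assume the time-scale separation of a T-channel (activation at least an
order of magnitude faster than inactivation) and 5-s conditioning
approximately reaching steady state; channels outside that regime will show
larger biases.

## The neuron model

The published firing simulations used a ModelDB thalamic-neuron
configuration that is not printed, so the cell is reconstructed as the
smallest model that expresses the phenotype: one compartment with
Traub-lineage transient Na$^+$ and delayed-rectifier K$^+$ kinetics (with a
threshold-shift parameter), a leak, and the T-type conductance in density
mode.  Three implementation decisions matter:

* **Voltage update.**  Gates use exponential updates; the voltage uses a
  linearized implicit (conductance-form) step,
  $v' = (v + \frac{dt}{c_m}(\sum g_x E_x + i_{inj})) /
  (1 + \frac{dt}{c_m}\sum g_x)$, which is unconditionally stable where
  forward Euler is not (total conductance reaches ~100 mS/cm$^2$ during
  the spike).  The default step is 0.0125 ms: at 0.025 ms the
  burst-ignition phase is not numerically converged (spike times move by
  ~2 ms under refinement), at 0.0125 ms a further halving moves spike
  times by < 0.1 ms with identical counts.
* **"Setting" the resting potential.**  The rheobase and train protocols
  define a resting potential of $-110$ mV.  This is implemented the way a
  current-clamp experimenter does it: a standing `holding_current()`
  makes $-110$ mV the resting point and the test pulse rides on top.
  (Merely clamping to $-110$ mV before the pulse would let the cell drift
  to its natural rest and fire regardless of the pulse.)
* **No deactivation table in the neuron.**  The model-parameter set of the
  published simulation comprises the activation/inactivation midpoints,
  slopes and time constants --- not the tail-deactivation constants.  The
  neuron's m gate therefore uses the activation table with constant
  extrapolation; the deactivation table only shapes simulated tail
  currents.  (Coupling the measured 10x tail slowing of I860N into its
  activation path at $-80$ mV would invert the published rheobase
  ordering.)

**Calibration.**  `scripts/calibrate_base_model.R` fixes the structural
constants first ($c_m = 1\,\mu$F/cm$^2$, area $1.43\times10^{-4}$ cm$^2$,
$g_{Na} = 100$, $g_K = 15$ mS/cm$^2$, $E_{Na} = +50$, $E_K = -80$,
$E_{leak} = -66$ mV, threshold shift $-45$ mV --- chosen so the spike
threshold sits above the low-threshold-spike plateau and the wild-type
rebound burst is transient), then tunes only $(g_{leak}, g_T)$ to the two
wild-type anchors --- rheobase 0.29 nA and rebound-burst $f_0 \approx
255$ Hz --- and freezes the result ($g_{leak} = 0.047$, $g_T = 1.00$
mS/cm$^2$).  All variant results are then predictions obtained by swapping
only the gating parameters.

**Firing metrics.**  `train_metrics()` defines train duration as
first-to-last spike peak, $f_0$ as the inverse first interspike interval,
and $f_{SS}$ as the mean inverse ISI over ISIs ending in the final 500 ms
of spiking (the published definition is not stated; this pins one).
`rebound_run()` calls activity *continuous* when it persists into the final
second of the 10-s run --- late spikes, or a maintained up-state /
subthreshold oscillation with mean voltage above $-60$ mV --- as opposed to
a return to rest.  `classify_firing_mode()` implements the low-threshold
firing (LTF) / slow oscillation (SO) taxonomy: SO requires at least one
second of contiguous spike-free trace sitting depolarized (mean $> -60$ mV)
with a 2--20 mV peak-to-peak oscillation.

## What the frozen model reproduces, and what it does not

With the frozen base cell, `reproduce_fig6()` recovers the published
rheobases within the documented 0.02-nA tolerance (0.29 / 0.23 / 0.20 /
0.19 / 0.19 nA against 0.29 / 0.22 / 0.20 / 0.19 / 0.18 for
WT / I860M / M1425I / I1306T / I860N), the strict severity ordering on a
fine current grid, the wild-type rebound $f_0$, and the published
continuous-vs-transient pattern of the free runs (continuous for I860M,
I1306T and I860N; transient for wild type and M1425I).

Known misses, reported honestly by the comparison table rather than hidden:

* Variant rebound $f_0$ comes out at 177--220 Hz against the published
  320--355 Hz, and train durations at 0.35 nA are longer than printed.
  Both depend on details of the original cell (morphology, additional
  conductances such as I$_h$ or Ca-activated currents) that are not
  printed and are out of scope here.
* The early-sweep persistent-current ratio of the AP-clamp protocol
  (I860N / wild type) comes out near 2x, not the published order of
  magnitude: the ratio and the (reproduced) facilitation-then-attenuation
  of the early AP peaks are both governed by the m-gate relaxation rate at
  the $-70$ mV inter-AP baseline and cannot be satisfied simultaneously
  in this reconstruction.
* In the TRN model the I860N free run is continuous *spiking* (LTF), in
  line with the published simulation; the pure slow-oscillation mode
  published for I860N belongs to the chromaffin-cell experiments, whose
  additional conductances are not modelled.

## A worked example

```{r example, eval = FALSE}
params <- cav33_params()

# voltage-clamp: activation shift of I860N vs wild type
wt  <- fractional_activation(simulate_sweeps(params$WT, make_iv_protocol()))
mut <- fractional_activation(simulate_sweeps(params$I860N, make_iv_protocol()))
v_half_shift(wt, mut)       # -15.6 mV: hyperpolarizing gain of function

# window currents
window_compare(params)[, c("variant", "peak_voltage", "area_ratio")]

# firing phenotype under the frozen TRN-style cell
find_rheobase(build_model(params$WT))     # 0.29 nA
find_rheobase(build_model(params$I860N))  # 0.19 nA
rebound_run(build_model(params$I860N))$continuous  # TRUE
```

## Limitations

No Markov (multi-closed-state) channel scheme, no temperature/Q10
correction, no GHK permeation by default, no series-resistance or
space-clamp artefacts, no multicompartment morphology, synaptic input,
I$_h$, or calcium-activated currents, and no stochastic gating.  The
synthetic parameter library is calibrated to published summary values, not
fitted to raw data; analyses of real recordings should treat it as a
reference model, not as ground truth.
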