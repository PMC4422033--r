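---
title: "Methods: stochastic Hodgkin-Huxley patches, exogenous noise, and SNR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic Hodgkin-Huxley patches, exogenous noise, and SNR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuronsr)
```

## The model

`neuronsr` simulates a patch of excitable membrane as a Hodgkin-Huxley (HH)
circuit in which the Na and K conductances are carried by *finite* numbers
of stochastic channels. The membrane equation, integrated by forward Euler
with step $\Delta t = 10\,\mu$s, is

$$C_m \frac{dV}{dt} = -g_{Na}(V_{tot} - V_{Na}) - g_K(V_{tot} - V_K)
  - g_L(V_{tot} - V_L) + I_0,$$

where $V$ is the physiological membrane voltage and
$V_{tot} = V + V_{ES} + V_{noise}$ is the total voltage seen by the
channels: the exogenous sinusoidal signal $V_{ES}$ and the exogenous
Gaussian noise $V_{noise}$ act as voltage sources in series with the
membrane. Both the gating rates and the ionic driving forces use
$V_{tot}$, while the capacitive term integrates $V$ only — the series
sources supply their own displacement current. We adopted this coupling
deliberately: treating the sum $V_{tot}$ itself as the integrated state
would make the perturbation cancel out of the dynamics entirely, leaving
the signal without any effect, whereas the series-source reading lets the
perturbation act on the voltage-dependent channels and feed back into $V$
through the ionic currents.

Conductances come from open-channel counts:
$g_{Na} = \gamma_{Na} N^{open}_{Na} / A$ and
$g_K = \gamma_K N^{open}_K / A$ with single-channel conductances
$\gamma_{Na} = \gamma_K = 20$ pS and patch area $A$. With the fixed channel
densities of 60 Na/µm² and 18 K/µm² this reproduces the macroscopic maxima
$\bar g_{Na} = 120$ and $\bar g_K = 36$ mS/cm². Patch areas of 200, 300 and
600 µm² give $N_{Na}$ = 12 000, 18 000 and 36 000 channels: the patch area
is the knob controlling the endogenous channel noise, whose relative
amplitude shrinks as $1/\sqrt{N}$.

Rate functions are the standard squid-axon set in the modern resting
convention (rest near $-65$ mV; $V_{Na} = 50$, $V_K = -77$,
$V_L = -54.4$ mV, $g_L = 0.3$ mS/cm², $C_m = 1$ µF/cm²). We chose this set
because it reproduces the deterministic repetitive-firing threshold
$I_{0th} \approx 6.3$ µA/cm² that anchors the distinction between
"impaired" ($I_0 = 2, 4$) and "healthy" ($I_0 = 7$ µA/cm²) stimulation
levels; `find_firing_threshold()` recovers it by bisection. The removable
singularities of the $x/(1 - e^{-x/k})$ rate kernels are replaced by their
analytic limits within $10^{-6}$ mV of the singular voltage.

## Stochastic channel tracking

Each Na channel is a Markov chain on 8 states (number of activated
m-particles 0-3 × h-particle state), each K channel on 5 states (activated
n-particles 0-4), with the canonical independent-particle transition rates
($(3-i)\alpha_m$, $i\beta_m$, $\alpha_h/\beta_h$; $(4-i)\alpha_n$,
$i\beta_n$). The simulator tracks the integer occupancy *counts* of the 13
states rather than individual channels. Per time step, for every occupied
state the numbers of channels taking each outgoing transition are drawn
jointly from a multinomial over $(r_1\Delta t, \ldots, r_k\Delta t,
\text{stay})$, and all states are updated from a snapshot. We use one
multinomial per source state, rather than independent per-transition
binomials, because it guarantees non-negative counts and exact conservation
in a single draw. At $\Delta t = 10\,\mu$s every exit probability is far
below 1 at physiological voltages; the pathological case is clamped with a
warning rather than silently renormalised.

Channel ensembles are initialised from the voltage-clamped stationary law
(product-binomial over particles) at the deterministic resting potential,
and the membrane starts at that resting potential; no burn-in is discarded
— records are analysed over the full 1 s, matching the reference protocol.
The choice of stationary initialisation removes the arbitrary transient a
fixed starting state would inject into every run.

Two independent oracles validate the scheme in the test suite: an exact
event-driven (Gillespie) simulation of the same chains for ensembles of
≤ 50 channels, and the 13-state master equation, whose expected-value
forward-Euler update the stochastic step reduces to when draws are replaced
by their means. The expected-value update, coupled to the voltage, is
verified to coincide with the classical $m^3h/n^4$ ODE model.

## Exogenous signal and noise

The signal is a weak sinusoid, default amplitude 500 µV, frequency 10-500
Hz. "Weak" is quantitative: without some noise source it cannot fire a
subthreshold neuron, and the tests check it leaves the mean firing rate
unchanged.

The exogenous noise is zero-mean Gaussian with a Lorentzian spectrum
$\mathrm{PSD}(f) \propto 1/(\omega_c^2 + (2\pi f)^2)$, cutoff
$\omega_c = 2.5 \times 10^3$ rad/s. It is generated by driving a discrete
single-pole low-pass filter — an AR(1) recursion with the exact pole
$a = e^{-\omega_c \Delta t}$ — with white Gaussian innovations. Two
numerical choices matter here:

* **Exact pole, not Euler.** Discretising the filter as $1 - \omega_c
  \Delta t$ distorts the cutoff and can go unstable; the exponential pole
  is exact at any step size.
* **Variance calibrated at the point of injection.** The innovation
  standard deviation is $\sqrt{D(1 - a^2)}$, which makes the *stationary
  variance of the filtered output* exactly the noise power $D$ (mV²), so
  the delivered noise has standard deviation $\sqrt D$. $D$ is the
  experimental knob swept in the stochastic-resonance analysis, so its
  meaning must be exact for the delivered voltage, not for the unfiltered
  driving process. The filter state starts from the stationary law and a
  warm-up of five filter time constants (2 ms) is discarded, so returned
  series are stationary from the first sample.

## Observables

Spikes are detected as upward crossings of 0 mV with a 2 ms dead time — a
criterion we fixed ourselves: 0 mV sits far above subthreshold
fluctuations and below every action-potential peak, and 2 ms is shorter
than the model's refractory period, so the detection is insensitive to the
exact values. Each run's spike train is converted to a pulse train $U(t)$:
100 mV in the 0.5 ms bin containing each spike, 0 elsewhere. The 0.5 ms
bin (2 kHz sampling) makes a 1 s record give 1 Hz spectral spacing with a
1 kHz Nyquist frequency, covering the 10-500 Hz signal band.

The spectral estimator is the plain one-sided periodogram (rectangular
window, no detrending), normalised so that the sum over frequencies times
the 1 Hz bin width equals the record's time-average power (Parseval; this
is asserted per run in the tests), averaged over $R$ replicate runs with a
per-frequency standard error. The reference protocol uses $R = 100$ with
channel noise alone and $R = 300$ when exogenous noise is present, because
the exogenous noise inflates the periodogram variance.

The signal-to-noise ratio at the forcing frequency $f_s$ is

$$\mathrm{SNR} = \frac{\overline{\mathrm{PSD}}(f_s)}
 {\tfrac12\left(\overline{\mathrm{PSD}}(f_s - 1) +
  \overline{\mathrm{PSD}}(f_s + 1)\right)},$$

with SNR = 1 meaning the signal is undetectable. Its standard error is
propagated to first order through the ratio using the full across-run
covariance of the three PSD bins; under sustained firing the adjacent bins
are strongly correlated (Pearson correlation around 0.9, reported by
`adjacent_psd_correlation()`), which makes the propagated error much
smaller than an independence assumption would give. A condition with no
spikes in any run has zero background; the SNR is then reported as a
flagged failed estimate rather than a number.

Total output power is the time-averaged square of the binned $U(t)$. Under
this discretisation it is proportional to the spike count, and the
proportionality constant depends on the arbitrary pulse width; absolute
power values are therefore reported but only power *ratios* between
conditions are treated as meaningful.

## Sweeps and reproducibility

`run_condition()` is the unit cell: $R$ seeded runs of one configuration,
processed one at a time so memory stays flat. `run_frequency_sweep()` and
`run_noise_sweep()` wrap it over the default grids {10, 50, 100, 150, 200,
300, 400, 500} Hz and {0, 0.7, 2, 4, 7, 12, 18, 25} mV² — grids we chose
to span the studied ranges and contain the reported optima; the reference
protocol does not fix the grid points. Every run, condition and sweep
cell receives an independent child seed derived from one master seed, so
identical configurations reproduce bit-identically and sweep rows equal
direct calls with the same child seed. No multiple-comparison correction
is applied to the per-condition standard errors; they are raw SEs, and are
reported as such.

## Problem sizes

The package's test suite runs most conditions at reduced replicate counts
(R between 15 and 80 depending on the check, chosen so each statistical
assertion retains a 3-standard-error band computed at the R actually
used); the SNR anchors are the exception and run at the reference R (100
or 300), because the SNR estimator's background denominator is too
heavy-tailed at smaller R to test a fixed band meaningfully. The channel
machinery is validated on small ensembles (20-50 channels) where the
exact Gillespie oracle is affordable. The acceptance
script `scripts/acceptance.R` runs the full reference protocol (R = 300,
or R = 100 for the suprathreshold condition).

## What the generator emulates — and what it does not

The synthetic inputs are exactly the study conditions: patch areas
{200, 300, 600} µm², currents {2, 4, 7} µA/cm², a 500 µV sinusoid at
10-500 Hz, and Lorentzian noise with $D \in [0.7, 25]$ mV². Passing tests
show that the simulator reproduces the statistical behaviour of this
idealised single-compartment patch — they say nothing about spatially
extended neurons, synaptic input trains, non-Lorentzian noise, or
temperature effects (no Q10 scaling is applied), all of which are out of
scope.

## Known limitations

* **Bistability at $I_0 = 7$ µA/cm².** For the standard parameter set the
  deterministic model is bistable between rest and the spiking limit cycle
  for $I_0$ between the saddle-node of cycles (≈ 6.26 µA/cm²) and the
  subcritical Hopf point (≈ 9.8 µA/cm²). With finite channel ensembles the
  trajectory intermittently drops off the limit cycle into quiescence and
  is re-excited by channel noise. At $I_0 = 7$ this produces mean rates of
  roughly 41-50 spikes/s across the three areas (deterministic limit cycle:
  59 spikes/s) — a spread of about 20% rather than area-independence — and
  caps the measured 150 Hz SNR of the 600 µm² patch near 5 rather than
  pushing it toward 7; at $I_0 = 8$, where dropouts are rare, the SNR
  reaches ≈ 6.7. Reported suprathreshold quantities should be read with
  this intermittency in mind.
* **Size of the stochastic-resonance improvement.** The SR effect is
  robustly present — at 300 µm² and $I_0 = 2$ the 150 Hz SNR rises from
  ≈ 1.5 without exogenous noise to ≈ 1.9 at $D = 12$ mV², and firing rates
  under noise rise several-fold — but the measured improvement
  (≈ 20%, about 2 pooled standard errors at $R = 300$) is smaller than the
  ~57% the reference results suggest, with the no-noise SNR a little
  higher and the with-noise SNR a little lower. The no-noise firing rates
  match the reference closely, which pins the endogenous noise level; the
  residual gap plausibly sits in unstated analysis conventions (spike
  criterion, background estimation) rather than the dynamics.
* **Absolute pulse-train powers** depend on the pulse discretisation and
  are not comparable across implementations; only ratios are.
* The SNR standard error is a first-order (delta-method) propagation; for
  very small $R$ or near-zero backgrounds it is only indicative.
* Divergent runs (|V| > 200 mV, never observed at the default step) are
  excluded with a warning rather than aborting a sweep.

## A worked example

```{r example, eval = FALSE}
model <- hh_model(area = 300, I0 = 2,
                  stimulus = stimulus_spec(0.5, 150),
                  noise = noise_spec(12))
res <- run_condition(model, R = 300, seed = 1)
res
res$snr
```
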