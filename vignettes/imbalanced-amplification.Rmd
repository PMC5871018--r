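---
title: "Imbalanced amplification: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalanced amplification: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbalnet)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the simulator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## The spiking model

The recurrent network holds $N$ adaptive exponential integrate-and-fire
(AdEx) neurons, $N_E = 0.8N$ excitatory and $N_I = 0.2N$ inhibitory,
driven by $N_X$ external Poisson neurons. Per-capacitance membrane
dynamics (all currents in mV/ms, so no capacitance constant appears):

$$\tau_m \dot V = -(V - E_L) + \Delta_T e^{(V - V_T)/\Delta_T}
  + \tau_m\,(X + R - w), \qquad \tau_w \dot w = -w,$$

with a spike recorded when $V$ crosses $V_{th}$, after which $V$ is held
for $\tau_{ref}$ and reset to $V_{re}$, $w$ jumps by $B$, and $V$ is
clamped below by $V_{lb}$. Defaults (`neuron_params()`): $\tau_m = 15$
ms, $E_L = V_{re} = -72$ mV, $V_T = -60$ mV, $V_{th} = -15$ mV,
$\Delta_T = 1.5$ mV, $\tau_{ref} = 1$ ms, $\tau_w = 150$ ms, $B = 0.267$
mV/ms, $V_{lb} = -100$ mV. Synapses are current-based exponential
filters $\eta_b(t) = e^{-t/\tau_b}/\tau_b$ with $\tau_E = 8$, $\tau_I =
4$, $\tau_X = 10$ ms; each kernel integrates to one, so the time
constants do not affect time-averaged currents. Inhibition is made
functionally fast ($\tau_I < \tau_E$) to avoid synchronous events that
destroy the balanced state.

Connectivity (`sample_graph`) draws, for each presynaptic neuron in
population $b$, exactly $\mathrm{round}(p_{ab} N_a)$ postsynaptic
targets in population $a$, uniformly **with replacement**; a neuron
drawn $m$ times receives weight $m \cdot J_{ab}$. Defaults: $p_{EE} =
p_{IE} = p_{IX} = 0.1$, $p_{EI} = p_{II} = p_{EX} = 0.2$, $J_{EE} =
0.4$, $J_{IE} = 0.83$, $J_{EI} = J_{II} = -1.67$, $J_{EX} = J_{IX} =
0.47$ mV. With $\tau_m = 15$ ms these weights span unitary PSPs from
0.195 mV (weakest) to 1.03 mV in magnitude (strongest), computable in
closed form with `psp_peak()`. Self-connections are permitted (nothing
in the sampling scheme excludes them). `scale_network()` changes $N$
while multiplying every $p$ and $J$ by $(5000/N)^{1/4}$, which preserves
every mean-field ratio and scales the balance parameter as
$\epsilon \propto N^{-1/2}$.

## Mean-field theory and the unit convention

With $K_{ab} = p_{ab} N_b$ and $\epsilon = 1/(K_{EX} J_{EX})$, the mean
input per population is $I = \epsilon^{-1}(W r + X)$ where $w_{ab} =
K_{ab} J_{ab}/(K_{EX} J_{EX})$ and $X = W_X r_X + s$. One unit
subtlety runs through the whole package: with rates in Hz,
$\epsilon^{-1}(Wr + X)$ carries mV/s, while simulator currents and the
printed stimulus amplitude $S$ are in mV/ms. The package therefore
converts in exactly two places: the rescaled stimulus is $s = 1000\,
\epsilon\, S$ (`external_drive`), and the gain matrix of the corrected
solver is $D = \mathrm{diag}(1000/g)$ for a user-facing gain $g$ in
Hz/(mV/ms) (`corrected_rates`). Mean-input fields are reported back in
mV/ms. $\epsilon$ itself is stored as the pure number $1/(K_{EX}
J_{EX})$ (its natural unit is 1/mV). The caption constant
"rheobase = 10.5" used to display currents in rheobase units is kept as
an opaque display divisor (`mean_currents(..., rheobase = 10.5)`); it
does not follow from the exponential-IF rheobase formula
$(V_T - E_L - \Delta_T)/\tau_m = 0.7$ mV/ms for these parameters and
affects no computation.

`balanced_rates` solves $Wr + X = 0$; it refuses matrices whose
smallest singular value is below $10^{-8}$ of the largest (condition
class `imbalnet_singular`), because no finite-current balanced state
exists there. Negative solutions are reported, not clipped — the linear
theory is only meaningful on the positive orthant. `corrected_rates`
solves $(\epsilon D - W) r = X$, which is finite even for singular $W$.
`nullspace_decompose`, `amplified_component` and
`partial_stim_expansion` implement the nullspace analysis; nullspace
vectors are signed so their first nonzero entry is positive, making
outputs reproducible. `near_singular_scale` extends the analysis to
approximately singular matrices via $\delta = |\lambda| + \epsilon$.

The gain $g$ is an input everywhere: the source publication never
prints its fitted value. Spiking runners fit it from their own
simulation (`fit_gain`: rectified-linear least squares with the slope
profiled out and the threshold found by a one-dimensional search);
mean-field-only runners use `default_gain()` = 15 Hz/(mV/ms), chosen
once as the value the package's own reference-scale full-stimulation
run fits (15.7–15.8 across seeds), and not revisited.

## Spatial networks

Continuously indexed networks place neurons on the unit square with a
uniform random preferred orientation on $[0,1)$ (fractions of
180°; "salt-and-pepper" map). Connection probabilities factor into
wrapped Gaussians in periodic physical distance and orientation
distance; the standard wrapped Gaussian
$\sum_j e^{-(u+j)^2/(2\alpha^2)}/\sqrt{2\pi\alpha^2}$ is used
(`wrapped_gaussian`, truncated at relative tail $10^{-12}$). Default
widths: $\alpha_E = 0.15$, $\alpha_I = \alpha_X = 0.04$ in space;
$\alpha_{E,\theta} = \alpha_{I,\theta} = 0.1$, $\alpha_{X,\theta} =
0.125$ in orientation (we read the printed
"$\alpha_{E,\theta} = \alpha_{E,\theta} = 0.1$" as covering both
recurrent populations, the only reading consistent with listing both).
Strengths carry a common factor 1.2, which cancels from every
$\bar w_{ab}$ and enters only $\epsilon$.

The mean-field convolution equations are solved in the Fourier domain
under the integral transform convention $\tilde u(n,k) = \int\!\!\int u\,
e^{-2\pi i (x\cdot n + k\theta)}$, realised by an FFT with $1/M$
normalization on the forward pass; mode cutoffs are the grid Nyquist.
Kernels become $\tilde w_{ab}(n,k) = \bar w_{ab} \exp[-2\pi^2(\|n\|^2
\alpha_b^2 + k^2 \alpha_{b,\theta}^2)]$. The corrected solution inverts
$\epsilon D - \tilde W$ mode by mode (2×2 closed form, vectorised over
modes); one derivation in the source writes the finite-size term as
$\epsilon g r$, but consistency with the discrete case and with the
displayed resolvent requires $\epsilon D r$ with $D = \mathrm{diag}(1/g)$,
which is what is implemented.

The balanced solution $\tilde r = -\tilde W^{-1}\tilde X$ needs care:
because $\tilde W(n,k) = \bar W\,\mathrm{diag}(d_E, d_I)$ factors by
presynaptic column, it is evaluated stably as $u_a e^{\Delta}\tilde
r_X$ with log-domain exponents. Two numerical policies apply
(`spatial_balanced_rates`):

* **Band limiting.** Modes where the input amplitude is below
  $10^{-13}$ of its peak are dropped before amplification. The balanced
  inverse grows exponentially with frequency, so beyond this band it
  would amplify the FFT noise floor of the input rather than signal.
* **Feasibility.** The solution is refused (class
  `imbalnet_infeasible`) when the retained mode amplitudes fail to
  decay — operationally, when the energy of $\tilde r$ over the top
  octave of retained mode radii is not below the previous octave. This
  square-summability test triggers exactly in the analytically
  infeasible regime $\beta_X < \alpha_E$ or $\beta_X < \alpha_I$, where
  input is sharper than recurrent connectivity.

The Gaussian width calculus (`gaussian_widths`) gives the balanced
profile widths $\sigma_E^2 = \beta_X^2 - \alpha_E^2$, $\sigma_I^2 =
\beta_X^2 - \alpha_I^2$ with $\beta_X^2 = \sigma_X^2 + \alpha_X^2$;
fitting a wrapped Gaussian to the solved profiles recovers these within
a grid spacing.

Stimuli (`build_stimulus`) follow
$r_X = \bar r_X\, [c + (1-c) G(x - x_0; \sigma_X)]\,[c_\theta +
(1-c_\theta) g(\theta - \theta_0; \sigma_{X,\theta})]$, with a
sharp-edged disc variant (indicator of radius $\sigma_X$, Gaussian edge
blur 0.01 by default) and an arbitrary contrast-map variant. In
calibration mode the floor $c$ and scale $\bar r_X$ are solved so the
spatial factor spans exactly 10–20 Hz over the grid, the stated
condition of the visual-cortex experiments; orientation uses $c_\theta
= 0.75$, $\sigma_{X,\theta} = 0.1$.

## What the simulator emulates, and what it does not

The compiled core integrates the network with forward Euler at
$dt = 0.1$ ms. Choices the source leaves open, fixed here:

* **Spike delivery** has a one-step ($dt$) delay; same-step delivery
  would make the Euler update depend on neuron ordering.
* **Refractoriness** pins the membrane at $V_{re}$ for $\tau_{ref}$
  (the membrane is described as "held" without a stated value; since
  $V$ is not recorded, only the ISI floor is observable).
* **Initial conditions**: $V \sim \mathrm{Uniform}(V_{re}, V_T)$ per
  seed, $w = 0$, synaptic filters 0; a 500 ms burn-in (configurable) is
  excluded from every average, and stimulation epochs additionally drop
  250 ms after onset.
* **Overflow safety**: the spike-initiation exponent is capped just
  above $(V_{th} - V_T)/\Delta_T$; the crossing test fires before the
  cap can matter.
* **Stimulation onset** defaults to half the simulation (the
  "second half" protocol) and is configurable.

Synaptic state is kept per neuron and kinetics class (three filter
states), decayed exactly by $e^{-dt/\tau}$ between events — this
matches the unit-integral kernel definition and is stable at the
working step size.

A green simulation test establishes that the *population-averaged,
time-averaged* behaviour of this particular point in parameter space
matches the linear theory (currents cancel; rates within 20% under the
self-fitted gain; the partial-stimulation sign pattern). It does not
probe spike-train variability or correlations, conductance-based
synapses, synaptic delays or depression, non-periodic boundaries,
structured orientation maps, or the stability of the balanced fixed
point — all outside this package's scope. The Fig-5-scale spatial
*spiking* network ($2\times10^5$ neurons) is likewise out of desk
scale; the spatial claims are checked at the mean-field level, with the
connectivity sampler validated distributionally at small $N$.

## Figure runners and remaining free parameters

`run_figure(1:7)` orchestrates: full stimulation, partial stimulation
($q = 0.2$, $S = 2$ mV/ms, seeded random targets), the two-layer chain
(upstream excitatory spikes become the downstream external population),
the weak-stimulus variant at $4N$ (where the stimulus amplitude is
deliberately a *required* argument — no value is published), the
spatial solutions for $\sigma_X = 0.2$ and $0.06$, size-tuning scans,
and the deconvolution demo. Durations and the unstated gain for the
spatial dashed-curve analogues are exposed as arguments. Every runner
can write its summary tables plus a JSON provenance record (seed,
parameters, package version).

## Known limitations

* The linear rate model is unbounded: for narrow stimuli at the spatial
  network's tiny $\epsilon$ it produces center rates far above
  physiological values; only the qualitative structure (amplification,
  suppression, extrema counts) is meaningful there, and the expansion
  flags negative leading-order rates as out of its validity domain.
* The corrected-to-balanced convergence in the spatial solver is
  pointwise but not uniform over modes; tests assert monotone decay
  rather than a uniform linear rate.
* `fit_gain` assumes a single shared gain across populations (the
  common-$D$ form); population-resolved gains are accepted by the
  solvers but not fitted.
* The one-dimensional nullspace formulas disable themselves (with an
  error) for multi-dimensional nullspaces; only orthonormal bases are
  returned in that case.
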