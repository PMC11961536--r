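---
title: "Detecting phage-induced lysis from QCM-D overtone spread: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phage-induced lysis from QCM-D overtone spread: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcmdlysis)
```

## The measurement and the statistic

A QCM-D sensor is a quartz disc oscillating in thickness-shear mode at a
fundamental frequency $f_0$ (here 5 MHz) and its odd overtones
$n = 3, 5, \dots, 11$. Adsorbing material shifts the resonance frequency
($\Delta f_n$, a mass proxy) and broadens it ($\Delta D_n$, the dissipation
factor, reported in $10^{-6}$ units, a viscoelasticity proxy). The shear
wave decays into the adjacent liquid over the penetration depth

$$\delta_n = \sqrt{\frac{\eta}{\pi\, n\, f_0\, \rho}},$$

about 140 nm at $n=3$ and 70 nm at $n=11$ in an aqueous medium at 25 °C.
A live bacterial film is soft and, acoustically, much thicker than
$\delta_{11}$: the low overtones sense a larger slice of it than the high
ones, so the **overtone spread**

$$\delta D = \Delta D_3 - \Delta D_{11}$$

grows with the effective film thickness. When an infectious phage lyses the
cells, the film collapses to thin, stiff envelope debris and $\delta D$
drops sharply; growth, medium flushes and non-infectious phage leave it
largely intact. Normalizing $\delta D$ to its maximum before the phage
injection removes the multiplicative sensor-to-sensor variability that makes
raw $\Delta D$ traces hard to compare.

The decision statistic is the sign of the mean (default) or sum of the
smoothed second derivative of normalized $\delta D$ over the period after
the final phage-free flush. The post-lysis trace decays convexly toward its
debris plateau (and, at low titer, turns upward again as survivors regrow),
giving mostly positive curvature; an undisturbed film saturates concavely
toward its carrying capacity, giving mostly negative curvature. Ties
(exactly zero) are called non-lytic. Two scalar readouts complement the
call: the *drop fraction* of normalized $\delta D$ across the injection
window, and the value at a fixed timepoint (240 min by default, after the
injection response has settled), compared across arms with a Welch
two-tailed $t$-test (unequal variances — appropriate because replicate
variance differs visibly between arms; the pooled-variance test makes an
assumption the data do not support).

## Assay phases and time conventions

The supported protocol is a seven-phase schedule: PBS baseline (20 min),
bacterial adsorption under flow (30 min), medium flush (15 min), static
growth (120 min), second injection of phage suspension or plain medium
(20 min), flush (15 min), static incubation (180 min); 30 µL/min during
flow phases. All durations are parameters of `default_schedule()`. Phase
windows are **half-open** $[t_\mathrm{start}, t_\mathrm{end})$ in minutes
from experiment start — a sample exactly at a boundary belongs to the later
phase — and the schedule object, not any hard-coded constant, defines the
normalization cut-off (the second injection's start, 185 min under the
defaults) and the classification window (after the final flush, 220 min).
Frequency shifts are stored raw, not divided by the overtone number: the
spread between raw overtones is the signal of interest, and $\delta D$ is
defined on raw traces.

## The synthetic-data generator

`film_trajectory()` integrates a latent surface state on the acquisition
grid (0.5 min step by default): fractional coverage $\theta$, live film
thickness $h_\mathrm{live}$, debris thickness $h_\mathrm{dead}$, and rigid
phage mass $m$. The pieces:

* **Adsorption** — $\theta$ rises as a saturating exponential (rate
  $k_a = 0.15\,\mathrm{min}^{-1}$, plateau 0.8) during the bacteria
  injection; the film starts at `h_adsorb` = 60 nm.
* **Growth** — logistic thickness growth during static phases
  ($r = 0.02\,\mathrm{min}^{-1}$, carrying thickness `h_cap` = 250 nm).
* **Flow losses** — each pumped phase shears off a 2% multiplicative
  fraction (`flush_loss`); a phage-bearing injection adds a transient 6%
  thickness loss (`phage_shock`), recovered by regrowth when no lysis
  follows.
* **Infection** — a Poisson encounter model gives the infected fraction
  $p = 1 - e^{-k_i \cdot \mathrm{titer} \cdot \mathrm{exposure}}$ over the
  injection window. With $k_i = 4\times10^{-7}$ mL/(PFU·min) and a 20-min
  exposure, $p \approx 1$ at $8\times10^7$ and $2\times10^6$ PFU/mL and
  $p \approx 0.96$ at $4\times10^5$ PFU/mL, which keeps the $\delta D$ drop
  nearly titer-independent while leaving visible survivor regrowth at the
  lowest titer.
* **Lysis** — one latency (`latency` = 17 min, a T7-like lytic cycle) after
  exposure begins, a fraction $p$ of the live film converts to debris that
  relaxes exponentially (`collapse_time` = 12 min) toward
  `h_debris` = 95 nm with softness `s_debris` = 0.42; survivors resume
  logistic growth at `survivor_regrowth_boost` (2×) the base rate.
  Softness is the thickness-weighted mix of live (1) and debris material.

`simulate_experiment()` maps the trajectory through two closed-form
kernels. Dissipation uses a penetration-depth saturation kernel,

$$\Delta D_n = A_D\, s\, \theta\, \frac{\delta_n\,(1 - e^{-h/\delta_n})}{\delta_3},$$

a deliberately phenomenological stand-in for continuum (Voigt-type)
viscoelastic modelling: it is closed-form, testable, and reproduces the
qualitative facts that matter here — $\Delta D_n$ non-increasing in $n$,
increasing in thickness, softness and coverage, and a spread
$\Delta D_3 - \Delta D_{11}$ that is non-negative and strictly increasing in
$h$. Frequency combines Sauerbrey loading by rigid phage mass with a
coupled-resonance term for discrete adhering bacteria,

$$\Delta f_n = -\frac{n}{C}\,m + \chi\, A_f\, \theta\, \frac{n}{3},$$

with $C = \sqrt{\rho_q \mu_q}/(2 f_0^2) \approx 17.7$ ng cm⁻² Hz⁻¹ and a
per-sensor sign $\chi$, since both signs of the bacterial $\Delta f$ response
occur in practice and $\Delta f$ is not a reliable cell count. Both channels
are scaled by a sensor sensitivity $\lambda$ and carry independent Gaussian
noise per sample.

### Calibrated and chosen defaults

Three defaults are calibrations to the magnitudes the assay is designed
around, fixed once and not revisited:

* `phage_mass_amplitude` is computed so the noise-free $\Delta f_3$ step
  across the injection window equals −60 Hz at the reference titer
  $8\times10^7$ PFU/mL (phage adsorption rate
  $k_m = 10^{-8}$ mL/(PFU·min)); at lower titers the step shrinks and slows,
  while a phage-free medium injection changes $\Delta f_3$ by well under
  5 Hz.
* `h_debris` = 95 nm and `s_debris` = 0.42 place the lysed film's
  normalized $\delta D$ plateau near 0.2, i.e. a drop of about 0.8.
* $A_D$ = 250 ($10^{-6}$ units) sets the dissipation scale so that the
  growth-plateau $\Delta D_3$ is ≈155×10⁻⁶ — the upper range reported for
  dense, soft bacterial films — which makes the relative noise of
  normalized $\delta D$ (noise SD 0.05×10⁻⁶ per channel sample) about 0.1%,
  comparable to the smoothness of published normalized-spread curves.

Sensor variability across replicates is emulated by
$\lambda \sim \mathrm{Lognormal}(0, 0.15^2)$ and $\chi = \pm 1$ with equal
probability; no distributional information exists for either, so these are
modest, symmetric choices. Noise defaults (0.5 Hz, 0.05×10⁻⁶) keep the
classifier accurate but not trivially so. The injection duration is 20 min
by default (the protocol's stated pumping time; a 30-min variant appears in
some run descriptions) and is an ordinary schedule parameter.

### What the generator does and does not emulate

It reproduces the population-level trace phenomenology: adsorption, growth
with increasing overtone spread, flush responses, a titer-calibrated
frequency step at injection, near-total collapse at high titer, survivor
regrowth at low titer, non-infectious exposures that recover to the control
band, and sensor-to-sensor scale/sign variability. It does **not** model
spatial heterogeneity or microcolonies, filamentation, nutrient-depletion
kinetics beyond the logistic cap, bulk-liquid viscosity steps at medium
changes, drift, or the conductance spectrum itself. Passing tests therefore
demonstrate that the *analysis* recovers planted structure under realistic
noise and variability — not that the generator is a quantitative model of
any particular instrument run. One known simplification: with the default
$k_i$, survivor regrowth is pronounced at $4\times10^5$ PFU/mL but weak at
$2\times10^6$, whereas real assays show it at both lower titers; pushing
$p$ low enough to regrow strongly at $2\times10^6$ would break the observed
titer-independence of the drop fraction, and the latter was kept.

## Numerical choices

* **Second derivative** — moving-average smoothing with halfwidth 5 samples
  (2.5 min at the default grid) keeping full windows only (the series loses
  a halfwidth per end; partial edge windows would let raw edge samples
  dominate the curvature statistic), then central second differences, with
  one-sided differences at the two ends. Exact for quadratics; the
  smoothing window is a parameter everywhere it is used.
* **Drop fraction** — the minimum is searched strictly after the reference
  sample at the injection start (so a rising trace yields a negative,
  unclamped drop) and up to 10 min past the final flush
  (`settling_buffer`), capturing post-flush settling before the plateau.
* **Degenerate inputs** — normalization refuses a non-positive
  pre-injection maximum ("degenerate baseline": no film formed); missing
  overtones, empty slice windows, non-monotone time and malformed files are
  explicit errors, never silent repairs.
* **Integration** — explicit Euler at the 0.5-min acquisition step; the
  kinetics are smooth and slow on that scale, and the latent state is
  clamped by construction ($\theta, s \in [0,1]$, $h, m \ge 0$).
* **Determinism** — every stochastic draw flows from an explicit seed;
  panels derive per-replicate seeds from one master seed, and the global
  RNG state is saved and restored around simulation.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated data:
single experiments are 801 samples × 5 overtones × 2 channels (400 min at
0.5 min); the robustness check uses a 50-replicate panel (25 infectious
across three titers, 25 control/non-infectious) and the separation check an
8-replicate mixed panel. These sizes match the scale of a realistic
screening batch while keeping a full suite run in the tens of seconds.

## Limitations

The dissipation kernel is phenomenological: it cannot recover film moduli,
and quantitative agreement with continuum viscoelastic fits is out of
scope. The classifier assumes the seven-phase protocol (it needs a
`second_injection` and `flush_2` to anchor its windows) and a uniform time
grid. The 240-min readout presumes a short lytic cycle; phages with long
latencies would need a later readout and a longer post-injection window.
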