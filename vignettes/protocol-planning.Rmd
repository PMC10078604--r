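---
title: "Planning ex vivo spin-echo protocols from relaxometry models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning ex vivo spin-echo protocols from relaxometry models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxoplan)
```

## The problem

Ex vivo diffusion MRI of fixed rodent brain suffers from short relaxation
times: fixation shortens both T1 and T2, and the long echo times needed for
strong diffusion weighting then cost most of the signal. Three preparation
factors push back: a lower fixative concentration and prolonged rehydration
(soaking in PBS) lengthen T2, while a gadolinium contrast agent introduced
by active staining shortens T1, allowing a short repetition time without
saturation — at the price of also shortening T2. Because the agent helps
through T1 and hurts through T2, its concentration has an interior optimum
that depends on the sequence timing. This package models each ingredient
and combines them to plan acquisitions that maximize SNR per unit scan
time.

## Models

**Relaxivity.** Adding a paramagnetic agent at concentration $c$ (mM)
increases the relaxation rates linearly (fast-exchange limit):
$$\frac{1}{T_i(c)} = \frac{1}{T_{i0}} + r_i\,c, \qquad i = 1, 2,$$
with baseline times $T_{i0}$ (ms) and relaxivities $r_i$ (1/(mM·s); the
unit conversion to 1/(mM·ms) happens inside `relaxation_time()` and nowhere
else). `fit_relaxivity()` estimates $(T_{i0}, r_i)$ from a cohort of
samples prepared at different concentrations, minimizing residuals in the
*time* domain so that the reported regression standard error is in ms; the
rate-domain linear regression (`fit_relaxivity_rate()`) is provided as a
cross-check and coincides exactly on noiseless data. The package ships
fitted records for nine ex vivo rat-brain preparations
(`load_relaxivity_records()`): corpus callosum, cortex and thalamus under
4% and 2% PFA with Gd-DTPA, and 2% PFA with gadobutrol.

**Spin-echo signal and SNR efficiency.** For a 90°–180° spin echo,
$$S(TE, TR) \propto \left(1 - 2e^{-(TR - TE/2)/T_1} +
  e^{-TR/T_1}\right) e^{-TE/T_2},$$
the `"full"` variant of `spin_echo_signal()`. The common approximation
$(1 - e^{-TR/T_1})\,e^{-TE/T_2}$ is the `"simple"` variant. Both are
exposed because published planning work does not always state which form
was used; the two agree within 1% whenever $TE \le 0.02\,T_1$ and
$TR \gtrsim 1.2\,T_1$, but diverge at short TR, exactly the regime
contrast-enhanced protocols live in — so the sensitivity is worth testing,
and the planner accepts either. The full variant follows the standard
derivation, with the half-echo correction exponential governed by $T_1$.
SNR efficiency is
$$\mathrm{SNR_{eff}} \propto \frac{S(TE, TR)}{\sqrt{TR}},$$
since scan time is linear in TR and SNR grows with the square root of time
spent averaging. Proton density is deliberately absent: all comparisons are
between protocols or preparations of the *same* tissue.

**Rehydration kinetics.** T2 recovery during soaking is modelled as the
minimal exponential with a plateau,
$$T_2(t) = a - b\,e^{-t/\tau},$$
(`fit_rehydration()`), and the practical answer — how long to soak — is the
time to reach 95% of the plateau $a$,
$t_{95} = \tau \log\!\big(b / (0.05\,a)\big)$ (`time_to_fraction()`). The
threshold is defined against the plateau itself rather than the recovered
span, matching how soaking endpoints are reported in practice.

**SNR estimation.** In a magnitude image the signal-free background is
Rayleigh distributed with SD $\sqrt{2 - \pi/2}\,\sigma_g$, so
`estimate_snr()` multiplies the naive ratio $\eta / \sigma_{\mathrm{noise}}$
by $\sqrt{2 - \pi/2} \approx 0.655$ to recover $\eta/\sigma_g$. The
background statistic is the plain $(n-1)$-denominator SD of magnitude
values, and measurements are meant for raw (pre-denoising) images, where
the Rayleigh assumption holds.

## The planners

`optimal_concentration()` maximizes
$\mathrm{eff}(c) = S(T_1(c), T_2(c), TE, TR)/\sqrt{TR}$ and returns, along
with the argmax, the contiguous interval over which efficiency stays above
95% of the maximum — the practically useful output, since any concentration
in the interval costs at most 5% of the attainable SNR. `optimal_tr()`
maximizes efficiency over TR at fixed TE (in the short-TE limit the optimum
is $TR = 1.2564\,T_1$, the root of $e^x = 2x + 1$, which the test suite
verifies). `efficiency_surface()` evaluates the whole (TE, TR, [CA]) grid
with the per-cell optimal concentration. `matched_tr()` inverts the signal
equation in TR to ask what repetition time another preparation would need
to match a reference signal, and `predict_snr()`/`scale_scan_time()` carry
measured SNR and scan time from one protocol to another.

All optimizers are deterministic: a coarse grid (about 1 mM / 5 ms spacing)
locates the bracket, then golden-section search (`stats::optimize`) or
bisection (`stats::uniroot`) refines it — to 0.001 ms for TR, 0.1 mM for
interval endpoints, and $10^{-9}$ ms for matched TR so that the returned TR
reproduces the reference signal to better than $10^{-6}$ relative.
Unimodality of the concentration profile (guaranteed for positive
relaxivities, where the T1 benefit saturates while the T2 penalty
compounds) is asserted on the coarse grid; a violation downgrades to a
warning and the component containing the argmax. Default search bounds are
[0, 100] mM and [TE, 10 000] ms, both overridable; an optimum on a bound is
flagged rather than silently returned.

A worked example with the packaged cortical 2% PFA record:

```{r plan}
rec <- load_relaxivity_records()
cortex <- get_relaxivity_pair(rec, "cortex", 2, "Gd-DTPA")
plan_protocol(cortex$t1, cortex$t2, te = 27, tr = 250)
```

## Fitting details

The relaxometry fitters (`fit_t2_decay()`, `fit_t1_recovery()`,
`fit_map()`) use Levenberg–Marquardt least squares (`minpack.lm`), with
deterministic scale-free initialization: the relaxation time from the
closed form of the two most-separated points, $S_0$ from the largest
signal. Exactly two points are inverted in closed form. Curves with no
decaying (or recovering) trend, or fitted time constants beyond $10^4$
times the sampled range, are flagged non-convergent — a sentinel `NA` in
maps, counted and excluded from ROI statistics, never imputed. There is no
baseline offset term in either model, and no Rician bias correction during
fitting; the phantom tests quantify the resulting bias instead (median
fitted T1 stays within 3% of truth at 1% noise on the default variable-TR
schedule). Echo truncation (`truncate_after`) is available for T2 fitting
but off by default: all echoes are used unless the user decides the late
echoes sit in the noise floor.

The rehydration fitter uses `stats::SSasymp` self-starting asymptotic
regression, with a Levenberg–Marquardt fallback from range-based starting
values (exactly noiseless data occasionally defeats the self-start's
internal linearization). An essentially constant series is returned
directly as amplitude 0 with an infinite time constant; monotone-decreasing
data yields a negative amplitude with a warning, and $t_{95}$ is then
undefined.

## What the phantoms emulate — and what they do not

`make_relaxometry_series()` generates voxelwise forward-model signals on a
labelled 32×32×4 phantom (three regions named CC/cortex/thalamus for test
readability, truths patterned on gadolinium-free 2% PFA tissue) and adds
Rician noise as the magnitude of a complex Gaussian pair; background
regions therefore carry Rayleigh noise, which the SNR-estimator tests
exploit. Default control values are the 22-echo (8–176 ms) and six-TR
(200–5500 ms) mapping schedules typical of ex vivo protocols. Cohort
generators add Gaussian noise *in the time domain* — on the tabulated
relaxation times, not on raw signals — which keeps the relaxivity
parameter-recovery tests interpretable; the recovery-test design uses the
perfusion concentrations {0, 15, 25, 35, 50} mM with two samples each and
50 ms noise. The rehydration truth used in tests is
$(a, b, \tau) = (52\,\mathrm{ms}, 22\,\mathrm{ms}, 7\,\mathrm{d})$,
giving $t_{95} = 14.9$ d, inside the 14–20 d window expected for 2% PFA
tissue ($\tau = 7$ d rather than a smaller constant precisely so that the
implied $t_{95}$ lands in that window); the 4%-pattern comparison truth
$(55, 25, 15)$ gives $t_{95} \approx 33$ d. Every generator is a
deterministic function of its spec and seed, and round-trips through the
corresponding fitter with zero residual at zero noise.

What the phantoms do *not* model: spatial correlation of noise, coil
sensitivity profiles, $B_1$ inhomogeneity, partial-volume mixing at region
boundaries, susceptibility effects near tissue–air interfaces, or any
diffusion weighting. Passing phantom tests therefore validates the
estimators' numerics and noise handling, not their robustness to
acquisition artefacts in real scans.

## Problem sizes

The test suite runs everything at desk scale: phantoms up to 320×320
voxels for noise-moment checks, 200-voxel Monte-Carlo maps, 100-replicate
cohort recoveries, and 20 random parameter sets for the
optimizer-vs-exhaustive-grid equivalence checks (0.1 mM / 0.5 ms grids).
These sizes were chosen to keep Monte-Carlo error comfortably inside the
asserted tolerances while the whole suite completes in well under a
minute.

## Known limitations

- The signal model covers standard spin echo only: no gradient-echo,
  inversion-recovery, echo-train or diffusion-attenuation terms. Protocols
  whose signal depends on flip angle, $T_2^*$ or b-value need their own
  objective.
- Relaxivities are field-strength specific; the packaged records describe
  9.4 T rat tissue and do not transfer to other field strengths.
- `predict_snr()` compares the same tissue across preparations; comparing
  different tissues would require proton-density ratios the model omits.
- Mono-exponential relaxometry only: no multi-compartment fitting, and no
  motion correction or registration — masks must already be voxel-aligned.
- Concentrations refer to the perfusate/rehydration solutions, not to the
  (lower, unobserved) concentration reached inside tissue; fitted
  relaxivities are effective, protocol-level parameters.
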