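---
title: "Model-based displacement mapping for MR-ARFI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based displacement mapping for MR-ARFI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arfimap)
```

## The problem

MR acoustic radiation force imaging (MR-ARFI) visualizes a focused
ultrasound (FUS) focus by encoding the tissue displacement produced by an
ultrasound pulse into the phase of MR images: the pulse is triggered during
a motion-encoding gradient (MEG), so a displacement $d$ sustained during a
gradient of strength $G$ (mT/m) and duration $T$ (ms) accrues phase

$$\theta = 2\pi \cdot 42.58 \cdot G \, T \, d,$$

about 0.015 rad for 200 nm at $G = 40$, $T = 7$. Displacements achievable
at acoustic pressures inside mechanical-safety limits are in the 100–200 nm
range, so the focal phase shifts are tiny and easily overwhelmed by
physiological and instrumental phase drift. The acquisition this package
targets alternates the displacement-phase contrast every timepoint — the
trigger switches between the two MEGs each repetition, so every consecutive
pair of images forms one "average" with opposite-signed displacement phase —
which minimizes the time between the two contrasts and freezes slow drift.

## The signal model

Each complex image timepoint $n$ is modeled per voxel $j$ as

$$\hat I_n(x_j) = m_j \, e^{\,i[(A c_n)_j + (-1)^{\mathbb{1}[n]}\, \theta_j]},$$

where $m$ is a complex baseline image common to all timepoints, $A$ is a
spatial polynomial design matrix (order 2 by default, 6 terms), $c_n$ are
per-timepoint coefficients absorbing smooth phase drift, $\mathbb{1}[n]$
indicates timepoints with negated contrast, and $\theta$ is the
displacement phase. The fit minimizes

$$\frac{1}{N_t}\sum_n \sum_j \bigl|I_n(x_j) - \hat I_n(x_j)\bigr|^2
  + \lambda \sum_j |\theta_j|,$$

where the L1 penalty encodes the prior that displacement occupies a small
minority of voxels, separating the compact focal spot from the smooth,
non-sparse drift the polynomial models. For fixed $(c, \theta)$ the optimal
baseline has the closed form

$$\hat m_j = \frac{1}{N_t}\sum_n I_n(x_j)\,
  e^{-i[(A c_n)_j + (-1)^{\mathbb{1}[n]}\theta_j]},$$

the mean of the images after removing the polynomial and displacement
phases, and `fit_arfi()` substitutes it at every loss evaluation so the
quasi-Newton optimizer (`optim`'s L-BFGS-B) only sees $\theta$ and the
$c_n$. Gradients are analytic.

Once $\theta$ is estimated, `result_to_map()` divides by
$2\pi \cdot 42.58 \, G T$ to produce meters. The constant 42.58 is used
verbatim as the conversion's gyromagnetic factor (not 42.5764), and the
single $G T$ product of the unipolar MEG pair is used as-is; both choices
keep the package's maps directly comparable with the convention the
sequence community uses for this conversion.

## Numerical design choices

**Coordinate normalization.** The polynomial basis is evaluated on
pixel-center coordinates normalized to $[-1, 1]$ per axis (plain monomials,
column 1 constant). Unnormalized pixel indices would make the joint
optimization catastrophically ill-conditioned at order 2 on a 256² grid.
Any full-rank reparameterization (Legendre, Chebyshev) yields identical
fitted phase fields; monomials keep the coefficients interpretable.

**L1 smoothing.** The penalty uses $|t| \approx \sqrt{t^2 + \varepsilon}$
with $\varepsilon = 10^{-8}$, because Wolfe line searches misbehave on
non-smooth objectives. Results are insensitive to $\varepsilon \le 10^{-6}$.

**$\lambda$ auto-scaling.** A working penalty weight of 2000 is appropriate
when the images have mean magnitude around $10^4$; since the data term
scales with the squared magnitude and the penalty does not, the default
`auto_scale_lambda = TRUE` multiplies the unit weight
`lambda_sparsity = 0.2` by the series' mean magnitude, reproducing 2000 at
amplitude $10^4$ while making the default amplitude-invariant.

**Preconditioning.** The data-term curvature with respect to $\theta_j$
scales with the voxel's mean squared magnitude, so air voxels are orders of
magnitude "flatter" than tissue voxels and unpreconditioned L-BFGS stalls
in its tail. The fit optimizes rescaled variables (each $\theta_j$ scaled
by its curvature's square root, analogously for the coefficients), which in
practice reduces a 64×64, 20-timepoint noiseless fit from thousands of
evaluations to a few dozen. The per-voxel scale is floored at 5% of the
mean squared magnitude: noise-dominated air voxels carry no phase
information, and fully equalizing their step sizes would let $\theta$ fit
noise there; with the floor they stay damped, consistent with fitting
without a spatial mask and leaving masks to the metrics. The objective
itself is normalized by the data energy so `gradient_tolerance` is
amplitude-invariant.

**Stable loss evaluation.** With the analytic baseline substituted, the
data term equals the total energy minus the baseline energy; evaluating it
that way loses all significant digits when the fit is nearly exact
(residuals of $10^{-6}$ of the signal). The implementation forms residuals
directly in the derotated domain, $|I_n e^{-i\phi_n} - \hat m|$, which is
cancellation-free.

**Gauge freedom and the final gauge step.** The decomposition is invariant
under $(\theta, c_n) \to (\theta - A b,\; c_n + (-1)^{\mathbb{1}[n]} b)$
for any coefficient vector $b$: a smooth field that flips sign with the
contrast schedule is indistinguishable from smooth displacement phase. At
$\lambda = 0$ this makes $\theta$ identifiable only modulo the basis span —
in particular, the schedule-correlated component of random drift can land
arbitrarily in $\theta$ — and at $\lambda > 0$ the penalty resolves the
ambiguity only asymptotically. `fit_arfi()` therefore ends with an exact
partial minimization over this flat direction: $b$ is chosen by an
iteratively reweighted least-absolute-deviations fit of $\theta$ on the
basis, which minimizes the L1 penalty over the solution family without
changing the data term (so it can only decrease the loss), and coincides
with the $\lambda \to 0^+$ convention when $\lambda = 0$. The gauge LAD
uses its own smoothing scale of $10^{-8}$ rad — far below any displacement
phase of interest — because reusing the penalty's $\sqrt{\varepsilon} =
10^{-4}$ rad scale would degrade the step to least squares on small fields.
Disable with `gauge_fix = FALSE`.

**Initialization and stopping.** $\theta = 0$, $c_n = 0$ (the baseline
then starts as the plain temporal mean): the zero-phase model is the
natural basin for sub-0.1 rad signals. History size 10, `maxit` 200
(heavily penalized objectives converge slowly near the L1 kink and may
need more), projected-gradient tolerance $10^{-8}$ on the normalized loss;
non-convergence returns `converged = FALSE` rather than an error. The
`loss_trace` records the best loss after each objective evaluation (the
underlying optimizer does not expose accepted iterates), so it is
non-increasing by construction.

**Per-slice fitting.** The model is fit per 2D slice; multi-slice data are
handled by looping the CLI over slice files. Joint multi-slice fitting
would require assumptions about through-slice drift coherence that the
model does not make.

## Reference estimators

`roi_corrected_map()` implements the classical correction: subtract each
image's complex-mean phase over a user-chosen out-of-focus rectangular ROI,
average the two contrast groups, and take the phase of
$\bar I_{\mathrm{pos}} \overline{\bar I_{\mathrm{neg}}}$. The package
halves that phase difference so $\theta$ is the per-image contrast phase
under the same convention and unit conversion as the model fit (the
alternative — not halving — differs only by a global factor of 2 and is a
documented convention choice). `epi_style_map()` implements the four-image
interleaved FUS-off/on × MEG-polarity difference-of-differences estimator
used by 3D EPI MR-ARFI protocols, again halved into the shared convention.
All phase differences are complex-conjugate products, never wrapped-phase
subtractions.

## What the simulator emulates

`simulate_series()` generates data through the same forward model plus
noise: a smooth complex baseline (soft-edged disk phantom at mean magnitude
$10^4$, with a random smooth baseline phase), a Gaussian focal displacement
spot (default 2.2 mm FWHM — a typical lateral focal width for a low-f-number
transducer near 650 kHz — and 200 nm peak), per-timepoint drift, and i.i.d.
circular complex Gaussian noise, under alternating, blocked, or epi4
schedules (for epi4, displacement phase enters only at FUS-on timepoints).

Drift has two parts, both AR(1)-correlated in time with $\rho = 0.9$
(slow, physiology-like evolution): second-order polynomial content inside
the model's span (stationary coefficient std 0.05 rad), and higher-order
smooth content built as a random fourth-order field minus its best
second-order approximation — guaranteeing content outside the span, which
is exactly the regime where the contrast schedule matters. The defaults
(noise std 100 per channel, i.e. magnitude SNR 100; drift amplitudes of
order 0.05 rad, comparable to or larger than the focal signal) were chosen
once as a realistic sub-safety-limit regime and are not tuned per analysis.

The simulator does **not** emulate: spiral k-space sampling and its
off-resonance/T2* blurring, coil structure, spatially sharp pulsatile
phase (vessels), motion between shots, or 3D focal geometry. Passing tests
on simulated data therefore demonstrate the estimator arithmetic and the
drift/schedule trade-offs, not robustness to every in-vivo artifact.

## Metrics conventions

An "average" is one consecutive opposite-contrast pair (one four-image
cycle for epi4); `subsample_averages()` always keeps averages intact and in
chronological order. Background statistics are computed over a brain mask
minus a focus-exclusion zone, defaulting to 3× the focal FWHM around the
focus center (a radius has to be chosen; 3× FWHM comfortably contains the
Gaussian spot's tails). `precision_curve()` derives per-cell seeds from the
root seed as `seed + 7919 * cell_index`, which keeps every cell independent
of list order and reproducible.

## Problem sizes used by the test suite

The packaged checks run single-slice problems: a 64×64 grid with 20
timepoints for the exact-recovery check, and 32×32 grids with 40–96
timepoints for the noisy-recovery, schedule-comparison, and averaging-law
checks (20 seeds / 10 resamples where repetition matters). These sizes were
chosen so the full statistical behavior — drift leakage, schedule
robustness, $1/\sqrt{N}$ averaging — is exercised at desk scale; the
estimators themselves are size-agnostic.

## Known limitations

- The displacement conversion assumes the tissue is displaced for the full
  MEG duration; partial overlap biases displacement low uniformly.
- The polynomial drift model cannot absorb spatially sharp temporal phase
  (e.g. pulsating vessels); such structure leaks into the residual and, if
  schedule-correlated, into $\theta$.
- At $\lambda = 0$ the reported $\theta$ is the minimal-L1 representative
  of an equivalence class (see the gauge discussion); any smooth component
  of true displacement that mimics the polynomial span is attributed to
  drift by construction.
- Heavily penalized fits (effective $\lambda$ well above the auto-scaled
  default) may need `max_iterations` beyond the default 200 to fully
  settle near the L1 kink.
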