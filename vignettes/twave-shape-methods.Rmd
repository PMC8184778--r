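---
title: "Statistical shape analysis of the V5 T-wave: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape analysis of the V5 T-wave: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twaveshape)
```

This vignette explains what `twaveshape` computes, why its defaults are what
they are, and what the synthetic validation does and does not demonstrate
about real electrocardiograms.

## The measurement model

A V5 beat is a function y(t) sampled at 1 kHz, in millivolts, over one RR
interval running from a P-wave onset to the next. The package's unit
convention is 1.0 = 1 mV and 1.0 = 1 ms throughout. After re-zeroing the
baseline (subtracting the straight line through the two P-onset anchors,
which leaves all second differences untouched), the repolarisation waveform
is summarised by nine landmarks. Two are defined on the raw trace — Q and J,
the first and last baseline intersections of the QRS complex — and the rest
on the smoothed derivatives: the extrema of y′ (steepest ascent and descent
of the T-wave, FdFmax and FdFmin), the first and second maxima of y″ (the
points of maximal bending on the two limbs, SdFmax and SdSmax), the apex Tp
(zero of y′ nearest FdFmin on its left), the tangent-method T-end Te, and a
reproducible stand-in for the visually chosen T-end, TeEye.

Curvature, κ = y″/(1 + y′²)^{3/2}, is computed pointwise. Because the
per-millisecond slope of a T-wave is of order 0.01, κ and y″ are numerically
interchangeable for landmark location; the package verifies their argmax
concordance on smooth beats rather than assuming it.

### Derivative estimation

Both derivatives come from cubic smoothing splines fitted to *first
differences*: y′ from the forward differences of y (placed at the left
node), y″ from the differences of the fitted y′. With a 1 ms grid the
differences are already in per-ms units. The first-derivative spline uses a
fixed smoothing parameter `spar = 0.5` on the conventional unit scale, which
`stats::smooth.spline` maps monotonically to the roughness penalty as
λ = r·256^(3·spar − 1) (r the trace-ratio normaliser of the penalised
regression matrices). The second-derivative spline selects its penalty by
generalized cross-validation, because differencing an already-smoothed curve
leaves noise whose level varies from beat to beat and is better handled
adaptively.

`spar_diagnostics()` reproduces the fitness/smoothness trade-off table:
for each candidate spar it reports the RMSE of the spline against the raw
differences and a differential-entropy estimate of the residual distribution
(histogram plug-in, Freedman–Diaconis bins — the entropy definition is a
package choice, as the diagnostic is qualitative). RMSE necessarily shrinks
as spar decreases; the table is meant for judging where further fitting buys
only noise, not for automated selection.

### Landmark detection order and tie rules

Detection proceeds FdFmax → FdFmin → Tp → TeEye → SdSmax → SdFmax → Te:

* FdFmax is the global maximum of y′ after J + 30 ms (the 30 ms offset
  excludes the J-point inflection itself); FdFmin the global minimum after
  FdFmax.
* Tp is the y′ zero crossing immediately left of FdFmin. If noise creates
  several candidate crossings near the apex, the one nearest FdFmin is used
  and a warning is issued — upright monophasic T-waves are assumed; bifid or
  negative T-waves are out of scope.
* TeEye is automated as the first grid point after FdFmin where |y| stays
  below 2% of the apex amplitude for 10 consecutive ms, evaluated on a 5 ms
  running mean so that sample noise at the threshold does not stall the
  scan. The definition is circular as stated in terms of SdSmax (SdSmax is
  searched up to TeEye, TeEye nominally starts at SdSmax); scanning from
  FdFmin resolves the circularity and is equivalent on a monotone descending
  limb, and the ordering TeEye ≥ SdSmax is verified afterwards.
* The tangent slope at FdFmin is taken from the smoothed y′, not raw
  differences, since the tangent construction belongs to the smoothed
  geometry.
* Every accepted beat must satisfy 0 = Q < J < SdFmax < FdFmax ≤ Tp ≤
  FdFmin < SdSmax; violations reject the beat with a diagnostic rather than
  silently reordering.

Q/J detection assumes the R peak is the global maximum of the
baseline-corrected beat (true for upright V5 morphology) and accepts samples
within 0.1% of the peak amplitude as "baseline", because an idealised
noiseless waveform has strictly positive tails and no literal zero crossing.
Manual override coordinates bypass detection entirely, mirroring
annotation-driven workflows.

### Rate correction and aggregation

Landmark x coordinates (ms from Q) are divided by √(RR/1000) — the Bazett
convention with RR in seconds. The source procedure writes only "√(RR)"; RR
in seconds is the standard dimensional choice and is flagged here as a
convention. The per-beat RR is the distance between the enclosing P onsets.
A case's configuration is the arithmetic per-coordinate mean of its
(typically 10) beats; Bazett correction is applied per beat, before
averaging. Correction is idempotence-guarded and never touches y.

## Shape analysis

### Procrustes registration

A planar configuration, centred, is a complex 9-vector; similarity
transformations are complex affine maps. Full GPA therefore reduces to a
rank-one Hermitian eigenproblem: the full Procrustes mean of unit preshapes
z₁…zₙ is the dominant eigenvector of Σᵢ zᵢzᵢ\*, which the package finds by
power iteration (tolerance 1e-10, cap 1000 iterations — the same fixed point
as the familiar align-and-re-average loop, but fast enough to sit inside
resampling loops). Each configuration is aligned by its optimal complex
similarity; the Riemannian distance to the mean is computed as
ρ = asin‖fit residual‖ rather than acos of the match cosine, because acos
near 1 loses half the machine digits and would spuriously floor ρ at ~1e-8
for identical shapes. The mean is rotated to match the raw average
orientation of the inputs so that output coordinates remain interpretable in
the input frame.

Tangent coordinates are the vectorised full-Procrustes fits projected
orthogonally to the four similarity directions at the mean (two
translations, scaling, rotation). The projection is explicit, so
orthogonality holds to round-off by construction; the tangent space has rank
2k − 4 = 14.

### Goodall's F and resampling

The F statistic scales the squared full Procrustes distance between group
means by the pooled within-group Procrustes sum of squares, with q = 2k − 4
numerator degrees of freedom. The tabular reference distribution assumes
isotropic, equal, small landmark variation — exactly what the null generator
`simulate_configurations()` produces, which is why the package can check the
test's size honestly (rejection rate at α = 0.05 within [0.035, 0.065] over
2000 replicates of 12 + 12 configurations). Real landmark noise is not
isotropic, so permutation (labels reshuffled) and bootstrap p-values are
first-class outputs, both with resolution 1/(iterations + 1) and an explicit
seed. Default iteration counts are 10000 for each. The bootstrap scheme —
the named test leaves it open — resamples cases with replacement within each
group after translating each group's fitted configurations to the pooled
mean, enforcing the null; it is documented here precisely because it is a
choice.

### PCA, ICA, discrimination

Shape PCA is the eigendecomposition of the tangent-coordinate covariance;
icon shapes displace the mean by c·√λ along a component (c = 1 by default,
the conventional "one standard deviation" display). ICA uses JADE: whiten
the retained PC scores (components covering ≥ 99.9% of variance, at most
n − 1), estimate the full symmetric-basis set of fourth-order cumulant
matrices, and jointly diagonalise them by Jacobi rotations. Components are
canonicalised deterministically — ordered by |excess kurtosis|, signed so
skewness is nonnegative — since ICA is only defined up to permutation and
sign. With near-Gaussian inputs the rotation is unidentifiable; the
decomposition still returns, with a warning keyed on the absence of
appreciable kurtosis.

A note on the JADE validation fixture: fourth-cumulant estimates from
heavy-tailed sources are noisy — with a Laplace source at n = 500 the Amari
separation index straddles 0.05 across seeds — so the recovery check uses
bounded sub-Gaussian sources (uniform and symmetric binary), for which the
estimator is well behaved and the index stays below 0.05 with margin. This
is a property of fourth-order ICA generally, not of this implementation,
which converges to exact recovery as n grows.

Discrimination is exhaustive best-subset logistic regression over
{s, ρ, PC1–PC3} or {s, ρ, IC1–IC3}, ranked by AIC = deviance + 2·(number of
coefficients), ties to fewer predictors. Complete separation — the expected
regime when a shape covariate cleanly splits 12 vs 12 cases — is *reported*,
never "fixed": the IRLS solver (epsilon 1e-8, 25-iteration cap) is allowed
to run to its cap, the near-zero attained deviance is reported, and the AIC
floor of 2·(coefficients) is the meaningful quantity. Coefficient magnitudes
under separation are solver artefacts and the package says so.

## The synthetic study

`simulate_beat()` renders a V5-like beat: a compact-support raised-cosine P
wave, a fixed-width (60 ms) triangular biphasic QRS whose first and last
baseline crossings give exact ground-truth Q and J, and an
asymmetric-Gaussian T-wave (independent left/right half-widths σL, σR). The
model is deliberately minimal: every derivative landmark has a closed form
(Tp at μ, FdFmax/FdFmin at μ ∓ σ, SdFmax/SdSmax at μ ∓ √3σ, tangent T-end at
μ + 2σR, TeEye at μ + σR√(2·ln 50) for the 2% threshold), which is what
makes the detection chain testable to ±3 ms. White noise, sinusoidal drift
and an optional 50 Hz component are added after the clean trace is anchored
to zero at its endpoints. P onsets are generator metadata, not detected.

The bundled study conditions are 12 cases per group, 10 beats per case, at
~900 ms RR (SD 50) and 5 µV noise; the late-onset group delays the T centre
by 60 ± 10 ms and lowers the apex to 0.4 mV mean (0.5 mV for controls), with
between-case SDs of 10 ms on the T centre and 0.05 mV on amplitude. Beat
parameters are drawn once per case; beats within a case differ only in noise
realisation, which is the natural reading of between-case biological
variation at this design size.

### What the synthetic validation shows — and does not

Passing tests demonstrate that the *chain of estimators* is correct: the
spline-derivative landmarks agree with analytic positions, registration is
exactly similarity-invariant, the shape test holds its size under its own
null, an injected 60 ms ST stretch is recovered as a group J→SdFmax interval
difference within 10 ms, and the stretched-and-lowered group is completely
separated by the shape covariates. They do not demonstrate robustness to the
things the generator does not emulate: bifid or biphasic T-waves, U-waves,
respiratory baseline wander beyond a slow sinusoid, muscle artefact,
beat-to-beat morphology change, or P-onset annotation error. Roughly 10% of
real recordings may be unanalysable for such reasons, and the package's
posture there is rejection-with-diagnostics, not silent repair.

One geometric subtlety deserves spelling out. In registered (unit-size)
shape space, the asymmetric-Gaussian model cannot move SdFmax *down* in the
late-onset group: every derivative landmark's height is proportional to the
apex amplitude, so lowering the amplitude rescales y uniformly, and the ST
stretch grows centroid size, which compresses all registered y — lifting
below-centroid points slightly. The characteristic lower-right displacement
of SdFmax is therefore asserted on the simply averaged, Bazett-corrected
group mean configurations (where the delayed-and-lowered T gives larger x
and smaller y robustly); a generator with genuinely independent limb heights
would be needed to express the registered-space version of the effect.

## Numerical choices, degeneracies, problem sizes

* GPA tolerance 1e-10 on the mean; degenerate (point-coincident)
  configurations and non-convergence are errors, not warnings.
* Goodall's statistic is flagged degenerate when the pooled within-group
  Procrustes SS falls below 1e-12 — identical copies within groups yield no
  valid F, and no p-value is fabricated.
* The thin-plate spline uses U(r) = r² log r with exact landmark
  interpolation; repeated source landmarks make the system singular and are
  rejected. Bending energy is the quadratic form WᵀKW summed over both
  coordinates, zero exactly for affine maps.
* The JZS Bayes factor integrates the Cauchy-prior (scale √2/2) marginal
  likelihood by adaptive quadrature (relative tolerance 1e-9), reported as
  log_e BF01 so that large negative values mean decisive evidence for a
  group difference.
* Confidence ellipses are Hotelling mean-confidence regions (radii
  √(eigenvalue·T²crit/n)), not data ellipses.
* Validation problem sizes were chosen to make the suite's statistical
  assertions sharp but cheap: 2000 replicates with 500 permutations each for
  the test-size check, 500 observations for ICA recovery, 12 + 12 × 10 beats
  for the end-to-end study — the whole suite runs in a few minutes on one
  core.

## Known limitations

Upright monophasic V5 T-waves only; no bifid/biphasic logic, no automatic P
or R delineation research, no 3-D vectorcardiography, no cross-validation or
regularised classifiers (in-sample AIC selection is the point, separation
included). The spar = 0.5 default was adopted from qualitative
fitness/smoothness balancing; `spar_diagnostics()` exists so users can
re-examine it on their own data rather than trust it blindly.
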