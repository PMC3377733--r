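---
title: "Unmixing Raman spectra with variable reference signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing Raman spectra with variable reference signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmix)
```

## The problem

A Raman measurement of a mixture is, to a good approximation, a linear
combination of the spectra of its constituents plus noise. Classical
least squares (CLS) therefore estimates constituent weights by
projecting the measured spectrum `m` onto a matrix of reference
spectra. The catch is that real reference signatures are not fixed:
repeated scans of the same nanoparticle solution or background
material show peak-amplitude changes, small peak shifts, and — for
paraffin-like backgrounds — a broad bump of variable magnitude near
1600–1800 cm⁻¹. When the analyte signal is weak relative to the
background, these variations dominate the error budget of the weight
estimates.

`ramanmix` implements three estimators of increasing sophistication
behind one tabular interface, plus the simulation machinery to compare
them:

* **LS-qP** (`cls_fit()`): CLS augmented with the q+1 basis columns of
  a q-th order polynomial (q = 3 by default), which absorbs smooth
  baseline drift but nothing structured.
* **HLA** (`hla_estimate()`): hybrid linear analysis. The analyte
  reference `S_A` is orthogonalized against the principal components
  of a background calibration set; the resulting calibration vector
  `b` annihilates background variability in that span, and
  concentration is read off as `b · (m − mean background)`.
* **HLP** (`hlp_fit()`): the hybrid least-squares/PCA estimator, which
  models variability in *every* reference — analyte included — and
  weighs how far each may flex by how much flexing the calibration
  data actually showed.

## The HLP model

Each compound k gets a variability model fitted by `fit_pca()`: mean
spectrum $\bar S_k$, orthonormal principal components $Z_{pk}$, and
eigenvalues $\lambda_{pk}$ equal to the sample variance (denominator
N−1) of the calibration spectra's projections onto each component.
The signal model lets each reference flex along its components inside
the weight multiplication:

$$x = \sum_k w_k \Big(\bar S_k + \sum_p c_{pk} Z_{pk}\Big).$$

With Gaussian measurement noise of standard deviation $\sigma$ and
independent zero-mean Gaussian priors on the coefficients with
variances $\lambda_{pk}$, maximizing the posterior over $(W, C)$ is
equivalent to minimizing the penalized cost

$$\|m - x\|^2 + \beta \sum_{k,p} \frac{c_{pk}^2}{\lambda_{pk}},
  \qquad \beta = \sigma^2,$$

so a deviation along a high-variance component is cheap and one along
a low-variance component is expensive, in exact proportion to the
variability observed during calibration. $\beta$ acts as the
hyperparameter; `hlp_config(beta_override =)` exposes it for
sensitivity analysis, and the $\beta \to \infty$ limit provably
collapses HLP onto CLS over the mean spectra.

The cost is biconvex and is minimized by block alternation from
zero-initialized coefficients:

1. **W-step.** With C fixed, form the effective references
   $\bar S_k + \sum_p c_{pk} Z_{pk}$ and solve the plain least-squares
   problem for W by minimum-norm pseudoinverse.
2. **C-step.** With W fixed, set $Q = m - \sum_k w_k \bar S_k$, build
   the design whose (p, k) column is $w_k Z_{pk}$, and solve the
   Tikhonov-regularized system
   $C = (A^\top A + \Gamma)^{-1} A^\top Q$ with
   $\Gamma = \mathrm{diag}(\beta / \lambda_{pk})$.

Each half-step is an exact minimization in its block, so the cost
trace is nonincreasing — an invariant the tests assert on every fit.
Starting with the W-step matters: with C = 0 the first W-step is plain
CLS, whereas a C-step from W = 0 would face an all-zero design (the
solver skips the C-step in that degenerate case). Components with a
numerically zero eigenvalue (below 1e-12 × the largest) are excluded,
which is the infinite-penalty limit.

### Stopping rule

The iteration stops when
$\max_k |w_k^{(n)} - w_k^{(n-1)}| \,/\, \max(\max_k |w_k^{(n)}|, 10^{-12})
 < \mathrm{tol}$, with tol = 1e-8 and a 500-iteration cap. The change
is measured relative to the **largest** weight magnitude, not each
weight's own: at trace concentrations the analyte weight fluctuates
around zero, where a per-component relative criterion never settles
even though the weight vector has long since converged to well below
any meaningful precision. In the factorial study below, every fit
converges under this rule, typically in a few hundred iterations.

### Choosing σ

`estimate_sigma()` implements the replicate protocol: measure one
static target N ≥ 2 times and return the root mean (over wavelengths)
of the per-wavelength sample variance. σ is a single scalar — no
wavelength-dependent noise weighting is attempted — and must be
positive for HLP to run. For synthetic studies the generator's
`noise_sigma` is the ground truth, and `study_config()` defaults its
`sigma` to the generator's default (0.02).

## HLA conventions

The calibration vector is normalized as $b = r / (r \cdot S_A)$ where
$r$ is the orthogonalized residual of $S_A$. Because the removed part
lies in the component span, $r \cdot S_A = r \cdot r$ and the two
normalizations found in the literature coincide; this one makes
$b \cdot S_A = 1$, so the dot product is unbiased on noiseless
mixtures and reads concentration in units of the reference. The mean
background is subtracted before the dot product: the component span is
annihilated by construction, but the mean is not, and leaving it in
would add the constant offset $b \cdot \bar S_{bg}$ to every estimate.

HLA defines no fitted spectrum of its own, yet residual diagnostics
need one. The package reconstructs the fit inside HLA's model space:
mean background + estimated weight × $S_A$ + the projection of what
remains onto the background component span; the Durbin-Watson
statistic is computed from the part no HLA term can represent.

## Diagnostics

* `durbin_watson()` computes
  $DW = \sum_i (e_i - e_{i-1})^2 / \sum_i e_i^2$ over the residual
  ordered by ascending wavenumber. DW ∈ [0, 4]; 2 means no serial
  correlation (white residual), values near 0 the structured residuals
  of an underfit model. The package's tests calibrate the statistic on
  white noise (mean within 0.02 of 2 over 10,000 draws) and probe the
  [0, 4] bounds by randomized search.
* `fractional_error()` is the **signed** relative deviation
  (est − true)/true. The signed convention is deliberate:
  over- and under-estimation are distinguishable in records, and
  summaries report mean, sample standard deviation (N−1), and mean
  absolute error per weight level.

## The synthetic generator

`generate_library()` emulates the variation modes seen in calibration
scans, not any particular instrument: each spectrum is a sum of
Gaussian peaks with per-spectrum amplitude scaling
(1 + N(0, `amplitude_jitter`)) and center shifts
(N(0, `shift_jitter`) cm⁻¹), plus an optional broad baseline bump with
normally drawn amplitude, plus i.i.d. Gaussian noise. Defaults, fixed
once as the package's study conditions:

* axis 400–1800 cm⁻¹ with L = 700 samples (the displayed range of
  typical SERS work; the code never assumes it);
* analyte: 8 narrow peaks (widths 8–18 cm⁻¹), amplitude jitter 3%,
  shift jitter 0.5 cm⁻¹ — nanoparticle signatures are comparatively
  stable;
* background (`background_generator_config()`): 5 broad peaks (widths
  30–60 cm⁻¹), amplitude jitter 10%, shift jitter 2 cm⁻¹, and a broad
  bump at 1700 ± 90 cm⁻¹ with amplitude 1.0 and sd 0.4 — the dominant,
  polynomial-resistant background variation mode;
* `noise_sigma` 0.02 against peak amplitudes of order 1.

What the generator does *not* emulate: cosmic-ray spikes, detector
nonlinearity, wavelength-calibration drift between sessions,
autofluorescence decay, or heavy-tailed outlier spectra. Passing tests
on synthetic data therefore demonstrate correctness of the estimators
under the stated variability model, not instrument-grade robustness.

## The factorial study

`run_factorial_study()` mirrors the standard characterization
protocol: for every combination of one analyte spectrum i, one
background spectrum j, and one weight v from the halving ladder
$2^0 \dots 2^{-13}$ (backgrounds are never weighted), the simulated
measurement is $v \cdot a_i + b_j$ and each estimator must recover v
using **leave-one-out** calibration — the analyte model from all
analyte spectra except i, the background model from all background
spectra except j. Leave-one-out models are computed once per excluded
index and cached, so a study costs $N_a + N_b$ PCA fits rather than
$N_a \times N_b$. Weights convert to concentrations via the reference
concentration (default 0.8, in nM for the motivating scenario, where
the dilution ladder spans 0.8 nM down to ~0.1 pM).

The package's acceptance study uses libraries of 10 analyte × 20
background spectra (2,800 combinations, ~8,400 fits), a size chosen so
the full three-method comparison completes in minutes on one core; the
full 106 × 476 grid (706,384 combinations) is supported through the
same interface and the `subsample` cap. On the default conditions the
study reproduces the qualitative ordering that motivates HLP: at the
two lowest weight levels the mean absolute fractional error of HLP is
below HLA's, which is far below LS-3P's, and the Durbin-Watson
distribution of HLP is right-shifted (closer to 2) relative to HLA and
especially LS-3P.

## Numerical choices

* Pseudoinverse: SVD with relative singular-value cutoff 1e-12;
  minimum-norm solution under rank deficiency, with a collinearity
  flag on the design.
* Polynomial block: Chebyshev basis on the axis affinely mapped to
  [−1, 1]; raw monomials in wavenumbers ~10³ would be catastrophically
  ill-conditioned at order 3.
* PCA sign convention: each component's largest-magnitude element is
  made positive, so serialized models and tests are deterministic.
* Calibration spectra are used as measured — no area or maximum
  normalization is applied, and none is exposed by default.
* Negative weights are reported unmodified; at trace concentrations
  their sign carries information and downstream maps conventionally
  mask them.
* All generator and study randomness flows from explicit integer
  seeds; generation restores the caller's RNG state.

## Limitations

* Gaussian noise likelihood only; a Poisson variant for
  photon-limited acquisition is out of scope.
* σ is scalar across wavelengths.
* The solver accepts any number of compounds K, but the shipped
  studies validate K = 2 (one analyte, one background).
* HLA's "estimate the backgrounds by subtracting known analyte
  contributions" calibration step is unnecessary here — background
  libraries are measured directly — and is not implemented.
* Vendor binary formats (SPC, WDF), despiking, and baseline
  pre-correction are out of scope; inputs are delimited text.
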