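---
title: "Quantitative gel densitometry with uncertainty bounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative gel densitometry with uncertainty bounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelquantr)
```

## The measurement problem

Agarose-gel electrophoresis separates nucleic acids by electrophoretic
mobility; densitometry converts the stained image into a one-dimensional
signal $h(m)$ along the normalized mobility axis $m$, and the area $S$ of a
band's peak is proportional to the amount $C$ of the corresponding
component.  Two obstacles stand between a peak area and a defensible
concentration statement:

1. every step of the processing chain — replicate alignment, averaging,
   baseline removal, separation of overlapping peaks, integration —
   transforms the raw-image errors in a way that is hard to anticipate, and
2. calibration standards of known composition often do not exist for complex
   mixtures, so the usual reproducibility-based uncertainty statements are
   unavailable.

`gelquantr` implements both regimes: closed-form uncertainty bounds when
standards are available, and propagation of image-level errors through the
full processing chain when they are not.

## Regime 1: calibration with standard samples

The calibration model for component $i$ with known concentration $C_i$
(relative standard error $\gamma_i$) and replicate peak areas
$\hat S_{ij}$, $j = 1 \dots n$, is

$$\hat S_{ij} = K C_i - \Delta S_i + \hat\varepsilon_{ij},$$

where $K$ is the sensitivity (area per unit amount), $\Delta S_i$ a
systematic offset — notably the negative bias induced by the sensitivity
threshold $C_{\min}$ below which results are censored to zero — and
$\hat\varepsilon_{ij}$ zero-mean random error.  Measurement of the unknown
sample yields areas $S_{ij} = K C_{\mathrm{act},i} - \Delta S_i +
\varepsilon_{ij}$ under the same threshold.  With $\hat M_i, M_i$ the two
replicate means, the two-equation system gives

$$\Delta S_i = K C_i - \hat M_i, \qquad
  C_{\mathrm{act},i} = C_i + \frac{M_i - \hat M_i}{K}
  = C_i\,\frac{M_i + \Delta S_i}{\hat M_i + \Delta S_i}.$$

`solve_c_act()` computes both algebraic forms and cross-checks them to
$10^{-10}$ relative.  `fit_sensitivity()` estimates $K$ by least squares over
all replicates of all components.  A single-intercept model is fitted
(`S ~ C`); per-component intercepts would make $K$ unidentifiable, since the
component means then absorb all between-concentration information.  The
per-component offsets are recovered afterwards from the means.  Censored
replicates are excluded from the fit, not treated as zeros, which would bias
$K$ downward: the censoring-induced bias is exactly what $\Delta S_i$
absorbs.

### Variance bounds and the error bound

Replicate scatter is summarized by `replicate_stats()`: mean, sample
variance (divisor $n-1$), variance of the mean, and a one-sided upper
confidence bound at probability $P$ (default 0.95),

$$V_{\max} = \frac{n-1}{\chi^2_{1-P}(n-1)}\,\sigma^2_{\mathrm{mean}},$$

whose inflation factor exceeds 1 at $P = 0.95$ and shrinks as $n$ grows.
This inflation is also the reason reproducibility statements from few
repeats are themselves uncertain: `sd_rel_uncertainty(30)` shows that an SD
estimated from 30 repeats may understate the truth by 28% at 95% one-sided
confidence.

Two bounds on the relative error of $C_{\mathrm{act}}$ are provided.
`bound_additive()` follows the additive decomposition:

$$\left|\frac{\Delta C_{\mathrm{act}}}{C_{\mathrm{act}}}\right| \le
  g\sqrt{\hat\gamma^2_{\mathrm{mean}} + \gamma^2_{\mathrm{mean}}} + \gamma_i,$$

with the coverage factor $g = 2$ by default (appropriate for distributions
close to normal at confidence 0.90–0.95; `coverage_simulation()` reproduces
this coverage empirically).  The first term is the type-A (statistical)
budget, $\gamma_i$ the type-B contribution of the standard.  Two
normalization conventions exist for the relative-variance terms: both over
the calibration mean squared, or each over its own mean squared.  Both are
implemented (`denominator = "calibration_mean"` / `"own_mean"`) rather than
silently harmonized; the default normalizes both by the calibration mean.

`bound_multiplicative()` follows the multiplicative decomposition and additionally
carries the relative uncertainty $\delta$ of $K$.  That term is correlated
with the calibration-mean errors; the conservative plain sum is used, so
the bound errs on the high side.

Two variance-of-the-mean divisor conventions appear in the two regimes:
$n-1$ for replicate areas, $n$ for image stacks.  Both are exposed
(`divisor_mode`, `mean_variance_divisor`) and neither is silently mapped to
the other.

`required_replicates()` solves the inverse problem — the smallest $n$ whose
additive bound meets a target, given pilot scatter — by upward scan, since
the $\chi^2$ quantile depends on $n$.  Near the type-B floor the answer grows
very fast (tens of thousands of repeats for a 0.1-point margin over the
floor), which quantifies how expensive accuracy beyond the standard's own
tolerance is.

## Regime 2: no standard samples

Without standards, the only source of an uncertainty statement is the
transformation of raw-image errors by the processing chain $C = f(I)$.  The
total error splits into the instrumental part transformed through $f$ and
the processing part: $|\Delta| = |f(I + \Delta_1) - f(I)| + \Delta_2$.

### The processing chain

1. **Alignment and averaging** (`align_offset()`, `build_stack()`).
   Replicates are registered by the integer offset maximizing the raw
   cross-correlation against the naive mean, in a single pass (an iterative
   mode exists).  Offsets are integer only: sub-pixel interpolation would
   correlate neighboring pixels and distort the variance model.
   Out-of-overlap pixels are cropped, never zero-padded, so no synthetic
   values enter the statistics.  The pointwise variance is computed about
   the *aligned* mean: deviations from the pre-alignment mean would count
   alignment blur as random scatter and report nonzero variance for
   noiseless jittered replicates.  Raw-product correlation is biased toward
   small offsets when a strong uniform background dominates the image; this
   is a documented limitation, and phantoms for alignment verification use
   background-free lanes.
2. **Profile extraction** (`extract_profile()`).  Row-wise sums (not means
   or medians) over the lane columns: areas must stay linear in amount for
   the calibration model, and sums propagate the pixel variances by simple
   addition under independence.
3. **Baseline removal** (`estimate_baseline()`).  The lower envelope of
   $h(m)$: a centered running minimum, smoothed by a running mean, clipped
   into $[0, h]$.  The window is monotone — enlarging it never raises the
   envelope.  A running minimum under a sloped background sits low by about
   (slope × half-window), which is precisely the kind of residual the
   systematic bound is designed to capture.
4. **Systematic bound map** (`systematic_bounds()`).  On mobility intervals
   declared analyte-free ("forbidden" regions), any residual
   $|h - h_0|$ bounds the possible systematic error of baseline removal.
   The map is extended to the full grid by the maximum observed forbidden
   residual — a deliberately conservative constant extension, needed because
   the bound must be evaluated on the peak carrier where no direct evidence
   exists.  Absolute values are used throughout, as the downstream bound
   consumes $|\Delta_{\mathrm{syst}}(m) - \bar\Delta_{\mathrm{syst}}|$.
5. **Peak separation** (`deconvolve_profile()`).  The recorded signal is a
   convolution $h = r * h_{\mathrm{act}}$ with the system impulse response
   $r(m)$; recovering $h_{\mathrm{act}}$ is a Fredholm problem of the first
   kind.  It is solved with the Tikhonov / minimal-modulus filter
   $H_{\mathrm{act}} = H R / (R^2 + \lambda)$ in a real transform domain —
   either even symmetrization plus a cosine transform, or the Hartley
   transform — so that the whole chain stays free of complex arithmetic.
   The plain spectral inverse rings (Gibbs effect); an
   alternating-projection iteration (`howard_iterate()`) clips negative
   values in the signal domain and restores the trusted passband
   coefficients (frequencies with $R^2 \ge \lambda$) in the transform
   domain, driving the negativity energy down while the stopband is filled
   in by the constraint.  A unit-area kernel leaves the zero-frequency
   coefficient untouched, so peak areas are conserved.
6. **Peak quantification** (`detect_peaks()`, `peak_area()`,
   `apply_threshold()`).  Local maxima filtered by topographic prominence;
   carriers run between flanking valley minima so that adjacent carriers
   share endpoints and trapezoid areas add exactly; censoring below
   $C_{\min}$ uses the strict inequality (the boundary value is reported).

### Choice of the regularization parameter

Generalized cross-validation is the default
(`select_lambda(method = "gcv")`): it requires no noise estimate and picks
$\lambda$ at the minimum of
$\mathrm{mean}((\tfrac{\lambda}{R^2+\lambda}H)^2) /
\mathrm{mean}(\tfrac{\lambda}{R^2+\lambda})^2$ over a log grid, falling to a
small floor on noiseless data (the inversion is then essentially exact).
The discrepancy (Morozov) rule is also provided, but on strongly
band-limited kernels the data misfit varies only weakly with $\lambda$ near
the noise level — and sits above it entirely once the net signal carries
non-convolutional content such as envelope kinks — which makes the selected
$\lambda$ unstable across realizations.  GCV was adopted as the default for
exactly this robustness reason; on validation phantoms it reproduces
overlapping peak areas within 2% and keeps the linearized random bound
within ~20% of the Monte Carlo spread.

### Propagating the errors

`forward_sensitivity()` pushes directional derivatives through every stage
(dual-value forward mode): the running minimum routes the derivative through
its argmin index, clipping zeroes it on the clipped branch, the transforms
and the Tikhonov filter are linear, and the non-negativity iteration is
replayed with its recorded branch pattern.  All tangent operations act
columnwise on a matrix of directions, so the full gradient is one batched
pass; results are independent of how directions are batched.  At kinks the
one-sided derivative of the evaluated branch is used.  Complex-step
differentiation — exact for analytic code — is retained as a validation
utility for smooth sub-chains; it cannot traverse the clipping and minimum
operations of the full chain, which is why dual-value propagation (identical
to complex-step on smooth regions) is the production engine.

The random-error bound follows from the pixel variance maps:

$$|\Delta_{\mathrm{rand}} C| \le g\sqrt{\sum_{x,y}
  \left(\frac{\partial f}{\partial I_{\mathrm{mean}}(x,y)}\right)^2
  \sigma^2_{\mathrm{mean}}(x,y)},$$

and the systematic bound from the forbidden-region map:

$$|\Delta_{\mathrm{syst}} C| \le \bar\Delta_{\mathrm{syst}} D +
  \sum_m \left|\frac{\partial C}{\partial f_h}\right|
  |\Delta_{\mathrm{syst}}(m) - \bar\Delta_{\mathrm{syst}}|,$$

with $D$ the carrier length of the quantified peak.  For a constant map the
second term vanishes and the bound is exactly $\bar\Delta D$.
`uncertainty_report()` assembles both, their sum as the total bound, and
optionally a Monte Carlo summary.

**Validity of the linearization.**  The running minimum is an order
statistic: its evaluated-branch derivative is only one-sidedly valid once
pixel noise is comparable to the margin between competing in-window minima.
Under such conditions the linearized bound can deviate substantially (both
ways) from the Monte Carlo spread; with a background slope that pins the
argmin and moderate noise, agreement is within ~10–20%.  The Monte Carlo
route is therefore not a luxury but the recommended cross-check whenever
noise is large relative to the background structure.

`monte_carlo_uq()` perturbs the mean image with an independent Gaussian
field of pointwise standard deviation $\sigma_{\mathrm{mean}}(x,y)$, plus —
when a systematic map is supplied — a fully correlated offset
$u\,\Delta_{\mathrm{syst}}(m)$ with a single $u \sim U(-1,1)$ per draw.
A systematic error is by nature common to all grid points, so one scalar
per draw is the faithful bounded-systematic model; independent per-point
uniforms would average out and understate the area bias.  The reported
central interval matches the nominal normal level of the coverage factor
($2\Phi(g)-1$).  Failed draws are excluded; more than 1% failures abort.

Processing the *mean* image, rather than averaging per-image results, is
both cheaper and better conditioned: the deconvolution stage is sensitive
to input errors, and $\sigma^2_{\mathrm{mean}} = \sigma^2/n$ is what enters
it.  The test suite verifies on phantoms that the mean-image route is no
noisier than the average of per-image results.

## The synthetic phantom generator

All validation rests on `gel_phantom_spec()` / `render_replicates()`
phantoms with known ground truth: per-lane Gaussian bands of known amounts,
blurred by a stated impulse response, on polynomial or exponential baseline
drift, with i.i.d. Gaussian pixel noise truncated at zero and integer-pixel
replicate jitter.  Conventions chosen once and kept:

- the mobility axis maps to image rows, normalized to $[0,1]$, larger row
  index = larger $m$;
- intrinsic band shapes are Gaussian (all oracle integrals analytic);
- jitter is integer-pixel, matching the integer-offset alignment search,
  and is recorded in the alignment convention (the offset that restores the
  unjittered frame);
- noise is additive Gaussian truncated at zero.  The truncation mimics
  non-negative detectors and biases low-intensity pixels: variance
  calibration fixtures therefore include a background pedestal above the
  noise floor, and the truncation is the reason background-level pixel
  variance in dim phantoms reads below the nominal $\sigma^2$.

The generator reproduces only the statistical structure the uncertainty
model assumes — not electrophoresis physics (no Ogston sieving, reptation,
voltage or temperature effects), no spatially correlated illumination
fields, no rotation or elastic deformation (alignment is rigid integer
translation only).  Passing tests therefore certify the processing and
uncertainty machinery under the stated error model, not robustness to
un-modeled physics.

## Numerical choices

- Transforms: the cosine route uses whole-point even extension (length
  $2N-2$) so the extension's DFT is exactly real; the Hartley route uses the
  cas basis directly.  On even-symmetric sequences the two coincide to
  machine precision.  As deconvolution routes they share the filter but
  differ in boundary topology (reflection vs circular wrap), so they agree
  to ~$10^{-5}$ relative away from one kernel half-width of the ends and
  are not bit-identical at the boundary.
- Convolution is linear (zero-padded by at least the kernel support), never
  circular: no wraparound artifacts.
- Kernel symmetry is enforced by averaging with the mirror — the reflection
  scheme requires an even kernel, and an even kernel is also what makes the
  Hartley convolution theorem pointwise.
- The non-negativity iteration stops on negativity energy below `tol`
  (default $10^{-10}$ of the initial signal energy) or `max_iter`;
  non-convergence returns a flagged result, never an error.  On noisy data
  the iteration approaches a limit set rather than a point; derivative
  checks against finite differences therefore use the prescribed
  $10^{-5}$-scale step and a generous iteration budget.
- Ties in the alignment argmax break toward the smallest $|dx|+|dy|$, then
  lexicographically — deterministic everywhere.
- All random draws derive from one master seed through fixed per-stage
  substreams; identical configuration and seed reproduce results
  byte-for-byte.

## Problem sizes used in validation

The shipped test suite runs phantoms of 48–200 rows and 12–36 columns with
2–100 replicates, profile grids of 100–600 points, 500 calibrate/measure
cycles at $n = 10$, Monte Carlo with 120–3000 draws, and $10^5$ draws for
the coverage-factor check; the full suite completes in well under a minute
on one core.  These sizes were chosen so each check exercises the relevant
asymptotics (variance shrinkage, coverage, linearization validity) while
staying convenient to run routinely.

## Known limitations

- Uneven illumination or strong flat background biases the unnormalized
  correlation alignment; normalize or background-subtract upstream if this
  applies.
- The systematic bound depends on the forbidden regions being truly
  analyte-free and representative of the background under the peaks; the
  constant extension is conservative but not a guarantee.
- The linearized random bound degrades when noise is comparable to the
  envelope's in-window margins (see above); use the Monte Carlo route.
- Mobility-scale calibration against ladder standards is out of scope; the
  mobility axis is the normalized row coordinate.
- Blind deconvolution is out of scope: the impulse response must be
  supplied or estimated from an isolated dilute band (`estimate_psf()`).
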