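---
title: "Mapping gray-matter microstructure with the return-to-origin probability: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gray-matter microstructure with the return-to-origin probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtopmap)
```

# The scientific problem

Cytoarchitectonic differences across cortical subdivisions — agranular,
dysgranular, and granular cortex in the insula being the canonical example —
have historically been accessible only post mortem. Multi-shell diffusion MRI
offers an in vivo proxy: the **return-to-origin probability (RTOP)**, the
integral of the normalized q-space signal,

$$\mathrm{RTOP} = \int_{\mathbb{R}^3} E(\mathbf{q})\, d^3\mathbf{q},$$

is the probability density that a water molecule returns to its starting
position after the effective diffusion time $\tau = \Delta - \delta/3$.
Restricted environments (small, densely packed cellular compartments) return
more molecules to their origin, so higher RTOP indicates more restricted
diffusion. We report the **normalized RTOP**, the ratio of tissue RTOP to the
RTOP of free water at the same diffusion time,
$\mathrm{RTOP} \cdot (4\pi\tau D_{\mathrm{free}})^{3/2}$, which is 1 for free
diffusion and dimensionless.

This package implements the full quantitative chain downstream of
minimally-preprocessed data: q-space reconstruction and RTOP estimation,
surface sampling and subdivision statistics with stability analysis, surface
gradient fields with directional statistics, seed-based connectivity-derived
target subdivisions, and canonical-correlation brain–behavior prediction —
with synthetic generators providing analytic ground truth for every stage.

# Signal model and RTOP estimator

## The MAP basis

The normalized signal is expanded on anisotropic Hermite functions
(the mean-apparent-propagator family): per axis,
$f_n(x) = H_n(x) e^{-x^2/2}/\sqrt{2^n n!}$ with $x_j = 2\pi u_j q_j$ in the
frame of a diffusion-tensor pre-fit, using products of even total order
$N_1+N_2+N_3 \le N_{\max}$ (50 coefficients at the default
$N_{\max} = 6$). The scale factors are $u_j = \sqrt{2\tau\lambda_j}$ from the
tensor eigenvalues (clamped to 0.1–3.0 × 10⁻³ mm²/s; isotropic fallback when
the tensor fit is degenerate), so a single Gaussian voxel with matching
scales is exactly the zeroth basis function. The fit is penalized least
squares with the analytic q-space Laplacian energy as the smoothness penalty;
the weight is chosen by generalized cross-validation over a log-spaced grid
(a fixed weight can be supplied). `rtop_from_fit()` evaluates the integral of
the fitted signal in closed form — a parity-signed sum over the all-even
coefficients divided by the scale volume — and is verified in the tests
against brute-force q-space quadrature of the fitted signal to 0.1%.

## Why a tail correction exists, and how it works

At the HCP-like maximum shell $b_{\max} = 3000$ s/mm², measurements only
constrain the ball $|q| \le q_{\max}$. For a Gaussian compartment with
diffusivity $D$, the fraction of its RTOP integral lying *outside* that ball
is $P(\chi^2_3 > 2 b_{\max} D)$ — 61% at $D = 0.3\times10^{-3}$ mm²/s. Any
estimator therefore extrapolates; the bare basis expansion decays with the
envelope of the tensor pre-fit, which systematically underestimates the tail
of mixtures containing slow pools (we measured 10–15% underestimation on
random mixtures by decomposing the integral into its in-ball and tail
parts).

`compute_rtop_map()` therefore estimates RTOP as **measured in-ball integral
plus extrapolated tail**: the in-ball part by quadrature of the fitted
signal (Gauss–Legendre radial rule times a Fibonacci sphere rule), and the
tail by per-direction radial extrapolation. Along each direction the signal
of any Gaussian mixture is completely monotone in $b$; the fitted values at
four equally spaced $b$-values determine a biexponential exactly via Prony's
method (pure linear algebra), whose radial Gaussian tails are analytic.
Physicality constraints — non-negative weights summing to at most $E(0)$,
diffusivities in 0.1–3.5 × 10⁻³ mm²/s, terminal-slope fallback for degenerate
directions — bound the extrapolation. On 20 random broad mixtures the
estimator agrees with the closed-form oracle to within 1.3% (the bare
basis-only estimate remains available via `tail_correction = FALSE`).

## Rician noise

Magnitude MRI noise is Rician and inflates weak signals toward the floor
$\sigma\sqrt{\pi/2}$. Pointwise corrections either bias the corrected value
downward (clamped moment correction) or amplify noise through the flat
region of the Rician mean (pointwise inversion) — both were measured and
rejected. The adopted scheme (`rician_correct()`): fit the basis to the raw
magnitudes (averaging the noise over all measurements), estimate $\sigma$
from the robust spread of the residuals, and apply the asymptotic inversion
$\sqrt{\max(\mathrm{pred}^2 - \sigma^2, 0)}$ to the *smoothed* predictions
before refitting. This is essentially unbiased wherever the local SNR
exceeds about 2 and is a no-op on noiseless data. On gray-matter-like
phantom voxels at b0 SNR 30, the median normalized RTOP across the phantom
shifts by about 4%. The limitation is physical and worth stating plainly:
signal below the noise floor is unrecoverable from single-voxel magnitude
data, so voxels dominated by very slow pools (deep partial-volume CSF
boundaries excluded from cortical masks in practice) remain biased under
noise.

# Surface statistics

RTOP volumes are sampled at mesh vertex coordinates (trilinear
interpolation, exact for linear fields; out-of-volume vertices excluded) and
averaged per functional subdivision with unweighted vertex means — an
area-weighted option exists but the unweighted mean is the default, matching
the averaging-across-vertices convention. The fine multimodal-atlas labels
are merged into the tripartite scheme (dAI = AVI ∪ MI ∪ FOP3; vAI = AAIC;
PI = PoI1 ∪ PoI2 ∪ Ig ∪ FOP2; everything else background).

The subdivision × hemisphere analysis is a two-way within-subject ANOVA
(subject as random factor, `aov` with `Error(subject/(subdivision*hemisphere))`
strata), reported with uncorrected degrees of freedom — with $n$ subjects the
subdivision and interaction effects carry df $(2, 2(n-1))$ and hemisphere
$(1, n-1)$; a from-scratch sums-of-squares implementation serves as the
oracle in the tests. No sphericity correction is applied by default, matching
the uncorrected-df convention for this design. Post-hoc paired t-tests cover
all within-hemisphere pairs and the between-hemisphere contrast per
subdivision, Bonferroni-corrected over the full contrast set.

**Stability analysis.** For each contrast and candidate sample size $N$,
`stability_analysis()` draws random subject subsets without replacement and
records the fraction reaching $p < \alpha$ with the full-sample sign. The
resample count (100) and the consistency criterion (95% of resamples
significant) are conventional reproducibility choices; both are arguments. A
planted paired effect of 1 standard deviation is declared stable by
$N = 25$ at $\alpha = 0.01$ under these settings.

# Gradient fields and directional statistics

Surface gradients use the standard piecewise-linear finite-element form per
triangle, averaged to vertices with triangle-area weights and re-projected to
the vertex tangent plane; boundary vertices are flagged invalid. The
per-region main direction is the normalized resultant of vertex gradient
unit directions (magnitude weighting available but off — whether empirical
main directions should weight by gradient magnitude is a modeling choice we
leave to the user).

Subject main directions are treated as vectors on the sphere: the Rayleigh
statistic is $S = 3N\|\bar{\mathbf{R}}\|^2$ against $\chi^2_3$ (three
degrees of freedom, one per component), dispersion is the circular standard
deviation $\sqrt{-2\ln \bar{R}}$, SEM is dispersion/$\sqrt{N}$, and the 95%
confidence half-width comes from a seeded bootstrap over subjects (2000
draws by default) — chosen over closed-form von Mises–Fisher intervals
because the underlying subject-direction distribution is not assumed.
Bootstrap CI coverage was measured at ≈0.95 for von Mises–Fisher samples at
the study's cohort size. Isocontours use marching triangles on the
piecewise-linear field with segments chained into polylines.

# Connectivity-derived target subdivisions

Motion screening follows the usual conventions: total displacement is the
maximum translation from the reference frame (the threshold 2 mm), and
framewise displacement sums absolute backward differences of the six
parameters with rotations converted on a 50 mm sphere (mean FD threshold
0.2 mm). Preprocessing is separable Gaussian smoothing (FWHM 6 mm on real
grids; smaller on phantom grids) followed by a zero-phase Butterworth
band-pass (order 2 run forward–backward, 0.008–0.1 Hz). Seed connectivity is
the OLS coefficient of the seed-mean regressor with intercept, global-mean
and six motion nuisance covariates. Group maps use one-sample t-tests with
Benjamini–Hochberg FDR across in-mask voxels.

Differential target subdivisions: for each seed, one-sided paired tests
against both other seeds, each FDR-thresholded ($p < 0.01$), combined with a
logical AND and intersected with the anatomical target mask. Because the two
one-sided tests of a pair cannot both reject, the three masks are disjoint
by construction (asserted at run time). An optional pre-mask by the
one-sample group map is available but off by default, since its role in the
construction is not uniquely determined.

# Brain–behavior canonical correlation

The brain block holds the six subdivision means (3 subdivisions × 2
hemispheres); the behavior block holds 11 measures. Subjects with any
missing behavioral cell are removed listwise with an exclusion log. CCA is
computed rank-aware (QR of each standardized block, SVD of the cross
product), so exactly collinear blocks are handled; Pillai's trace
$V = \sum \rho_i^2$ uses the standard approximate-F transform, with a
seeded permutation option. Sign indeterminacy is resolved per axis by
forcing the largest-magnitude brain weight positive and keeping canonical
correlations non-negative — applied per fold in cross-validation so
predictions align across folds. The reported first-axis association is the
Pearson correlation between the canonical variate *scores* (weights are
fixed vectors and cannot correlate across subjects); it equals the first
canonical correlation by construction and is asserted to 1e-10.
Leave-one-out prediction standardizes with training-fold statistics only and
scores the held-out subject on the training weights; Cohen's d uses
$d = 2r/\sqrt{1-r^2}$. Behavioral columns enter untransformed; a transform
can be applied upstream of `fit_cca()` if reaction times warrant it.

# The synthetic generators: what they emulate and what they do not

* `make_acquisition_scheme()` mirrors a 3-shell HCP-like protocol
  (b = 1000/2000/3000 s/mm², 90 directions per shell, 6 b0, τ ≈ 39.7 ms);
  all parameters are arguments.
* `gaussian_compartment()` mixtures have closed-form RTOP — an exact oracle
  beats approximate realism for testing; restricted-pore models are out of
  scope. `random_mixture()` spans a deliberately broad diffusivity range
  (0.2–2.8 × 10⁻³ mm²/s) as the estimator stress-test;
  `random_gm_mixture()` is the cortical gray-matter tissue model (MD
  0.5–1.3 × 10⁻³ mm²/s, mild anisotropy, occasional 2–10% CSF partial
  volume) used by the volumetric phantom. Noise is Rician with SNR defined
  on the b0 signal.
* `make_surface_phantom()` is an open rectangular sheet (60 × 30 mm per
  hemisphere) with three contiguous subdivisions and a planted linear field
  along a chosen axis — the analytic gradient is the tangential projection
  of that axis. Insula-like curvature and closed topologies are
  deliberately absent: the gradient operator is tested separately on curved
  sheets, and flat sheets make the planted direction exact.
* `make_rest_phantom()` plants three disjoint target zones, each correlated
  with exactly one seed (coupling 0.6 by default), a weak global component,
  and sub-threshold motion drift.
* `make_brain_behavior()` plants a single canonical pair through one latent
  variable per block (latent correlation = the planted canonical
  correlation; column noise 0.3 of the latent scale). At the study's
  missing-data rate (1.5% of 413 subjects) six subjects carry a missing
  behavioral cell.

Passing on these phantoms demonstrates the *machinery* — estimator accuracy,
test calibration, recovery of planted structure — not the anatomy: real
cortical meshes are curved and folded, real fMRI noise is autocorrelated and
physiological, and real behavioral data are non-Gaussian. Headline empirical
values from a 413-subject cohort (specific F values, a Rayleigh statistic of
several hundred, specific canonical correlations) depend on the real data
and are not reproduced by phantoms; what is reproduced is every analytic
quantity (degrees of freedom, effect-size conversions) and every calibration
and recovery property at phantom scale.

# Numerical choices and degenerate inputs

* Hermite moment tables for the Laplacian penalty are computed once per
  radial order by fine trapezoidal quadrature (integrands decay like
  $e^{-x^2}$; accurate to ~1e-12) and cached.
* Voxels with non-positive estimated RTOP are flagged, not clamped, and are
  excluded from region means.
* Zero-area triangles are excluded with a warning (error if all are);
  degenerate main directions (resultant below 1e-8, e.g. antipodal
  cancellation) are an error, not a silent zero.
* Zero-variance voxels in group tests get p = 1 and a flag. Rank-deficient
  regression designs and degenerate CCA columns raise errors naming the
  offending columns.
* The pipeline demonstration sizes (5×5×4 dMRI grid, 400-vertex sheets,
  60 parcel subjects, 50 gradient subjects, 12 rest subjects of a 14×12×10
  grid × 180 frames, 400 CCA subjects) were chosen so a complete run with
  report takes well under a minute on a laptop core while every stage still
  has enough data to recover its planted truth; all sizes are configuration
  keys.

# Known limitations

* RTOP at $b_{\max} = 3000$ s/mm² is part measurement, part model-based
  extrapolation; the tail estimator is exact for two-compartment directional
  profiles and a close bound otherwise, but voxels dominated by sub-floor
  signal under noise are biased (see the Rician section).
* The GIFTI reader/writer covers POINTSET/TRIANGLE/LABEL/SHAPE arrays with
  ASCII and (GZip-)Base64 little-endian payloads — sufficient for exchange
  with the common surface tools, not a complete implementation of the
  format.
* Normalization is applied per voxel before surface averaging; averaging
  unnormalized RTOP and normalizing afterwards would differ only by a
  constant factor at fixed τ, but the per-voxel convention is the one
  implemented and documented.
* The rest-phantom connectivity analysis assumes aligned grids across
  subjects (no registration is performed anywhere in the package).
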