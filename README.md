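# rtopmap

Gray-matter microstructure mapping with the return-to-origin probability
(RTOP), for neuroimaging researchers linking cortical cytoarchitecture to
functional organization and behavior.

## The problem and the quantity

Cytoarchitectonic variation across cortical subdivisions — the agranular →
dysgranular → granular progression of the insula being the textbook case —
has classically required post-mortem histology. Multi-shell diffusion MRI
provides an in vivo proxy. The return-to-origin probability is the integral
of the normalized q-space signal,

    RTOP = ∫ E(q) d³q        (mm⁻³),

the probability density that a diffusing water molecule returns to its
origin after the effective diffusion time τ = Δ − δ/3. More restricted
tissue (smaller, denser cellular compartments) returns more molecules, so
higher RTOP means more restricted diffusion. Results are reported as
**normalized RTOP** — tissue RTOP divided by free-water RTOP at the same τ,
i.e. RTOP · (4πτD_free)^{3/2} — which equals 1 for free diffusion.

The signal is reconstructed with the anisotropic Hermite-function (MAP)
basis under analytic Laplacian regularization; RTOP follows from the basis
coefficients in closed form, plus a per-direction biexponential (Prony)
extrapolation of the q-space tail beyond the sampled maximum shell. The
package then carries the quantity through the full downstream analysis:

* **surface statistics** — volume-to-surface sampling, per-subdivision means,
  two-way repeated-measures ANOVA (subdivision × hemisphere), Bonferroni
  post-hoc paired t-tests, and subsampling stability analysis (minimum
  sample size that consistently reproduces a contrast);
* **gradient analysis** — finite-element surface gradient fields, per-region
  main directions, spherical directional statistics (dispersion, SEM,
  bootstrap CI) with the Rayleigh uniformity test (S = 3N‖R̄‖², df = 3), and
  marching-triangle isocontours;
* **connectivity subdivisions** — motion screening, smoothing + band-pass,
  seed-based regression betas with nuisance covariates, FDR-corrected group
  maps, and differentially connected target subdivisions (paired one-sided
  tests, logical AND, disjoint by construction);
* **brain–behavior CCA** — rank-aware canonical correlation between the six
  subdivision means and 11 behavioral measures, Pillai's trace with
  approximate-F (and permutation) significance, Cohen's d = 2r/√(1−r²), and
  leave-one-out prediction of the first canonical pair;
* **synthetic generators** for every input — Gaussian-mixture diffusion
  voxels with closed-form ground-truth RTOP, surface sheets with planted
  gradients, resting-state runs with planted seed-specific connectivity,
  and brain–behavior tables with one planted canonical pair — so the whole
  pipeline is testable without any download.

## Worked example

```r
library(rtopmap)

## HCP-like 3-shell acquisition
sch <- make_acquisition_scheme(c(1000, 2000, 3000), 90, 6, 10, 43, seed = 1)
print(sch)
#> Multi-shell acquisition scheme
#>   measurements: 276 (6 b0)
#>   shells (s/mm^2): 1000, 2000, 3000
#>   delta = 0.01 s, Delta = 0.043 s, tau = 0.0396667 s

## a gray-matter-like voxel: anisotropic + isotropic compartment, SNR 30
tissue <- list(gaussian_compartment(0.7, diag(c(1.2, 0.8, 0.6)) * 1e-3),
               gaussian_compartment(0.3, 0.7e-3))
sig <- simulate_voxel_signal(sch, tissue, snr = 30, seed = 2)
m <- compute_rtop_map(sig, sch)
m$normalized_rtop                                        # 7.651
normalize_rtop(rtop_oracle(tissue, sch$tau), 3e-3, sch$tau)  # truth: 7.454
```

The estimate (7.65) sits within ~3% of the closed-form ground truth (7.45)
despite Rician noise; values of 7–8 mean diffusion seven- to eight-fold more
"returned" than free water, typical of packed gray matter at this diffusion
time. Group-level gradient analysis on a planted surface phantom:

```r
ph <- make_surface_phantom(400, gradient_direction = c(1, 1, 0),
                           noise_sd = 0.15, seed = 3)
dirs <- t(sapply(1:50, function(s) {
  f <- ph$left$planted_field + rnorm(length(ph$left$planted_field), sd = 0.15)
  main_direction(mesh_gradient(ph$left$mesh, f),
                 ph$left$labels != "background")
}))
directional_stats(dirs, seed = 1)
#> group mean direction: (0.721, 0.693, 0.000)   # planted: (0.707, 0.707, 0)
#> dispersion 0.052 rad, SEM 0.0073
#> Rayleigh S = 149.6 (df = 3, p = 3.21e-32)
```

The 50-subject mean direction lands within a degree of the planted
anterior–posterior/ventral–dorsal axis, and the Rayleigh test decisively
rejects directional uniformity.

The end-to-end demonstration writes every intermediate in standard formats
(NIfTI, bval/bvec, GIFTI, CSV, JSON) plus a recovery report and manifest:

```r
run_all(pipeline_config(out_dir = "demo-run", seed = 1))
```

or from a shell: `Rscript inst/cli/rtop-pipeline.R all --out demo-run --seed 1`.

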