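# lumispat

Micro-scale spatial statistics for gut microbiota imaging.

Bacteria in the gut lumen are not well mixed: fluorescence microscopy of
cecum content shows micrometre-scale, single-species clusters, most simply
explained by cell division in a gel-like digesta that holds daughters in
place between the gut-wall contractions that periodically fluidize and
re-mix the content. `lumispat` packages the quantitative machinery needed
to measure and model this phenomenon:

* **Cell detection** — from a grayscale fluorescence image to per-cell
  coordinates and areas: white top-hat background removal, mean-relative
  thresholding, 8-connected labeling, morphological single-cell filters
  (area, eccentricity, solidity), removal of large elongated
  autofluorescent food particles, and splitting of touching-cell clusters
  by thin-edge detection with dilation/erosion.
* **Spatial statistics** — the inhomogeneous Ripley functions with border
  correction,

  K̂(r) = [ Σ_{i: b_i ≥ r} λ̂(x_i)⁻¹ Σ_{j ≠ i, d_ij ≤ r} λ̂(x_j)⁻¹ ] /
  [ Σ_{i: b_i ≥ r} λ̂(x_i)⁻¹ ],

  with L(r) = √(K(r)/π) and H(r) = L(r) − r, so H > 0 flags clustering,
  H < 0 regularity, and H = 0 complete spatial randomness (CSR). Local
  intensities λ̂ come from a leave-one-out Gaussian kernel estimate with
  window-edge correction. Summaries from several images are ratio-pooled
  (sums of numerators over sums of denominators) with a pointwise
  t-interval band, the H-peak radius reads out the typical cluster radius
  (argmax H / 2), and groups of images are compared with a Studentized
  permutation test on their H curves over r ∈ [0, 20] µm.
* **Community divergence** — Jensen-Shannon divergence between
  relative-abundance profiles, pairwise distance matrices, and the
  base/base vs tip/tip vs base/tip site comparison with one-sided
  Mann-Whitney U tests.
* **Rheology** — yield-stress estimation from oscillatory amplitude
  sweeps (intersection of power-law fits of stress vs strain below and
  above yield), G′/G″ crossover location, creep-fluidization
  classification, and replicate summaries (mean ± SD).
* **Contraction-mixing model** — Stokes' second problem for an
  oscillating gut wall under a Newtonian approximation of the digesta:
  velocity and shear-stress fields, the wall stress amplitude Aω√(ρωμ),
  and the mixing depth D = −√(2ν/ω)·ln[τ_yield/(Aω√(ρωμ))] at which the
  decaying stress amplitude falls to the digesta's yield stress.
* **Synthetic data** — generators for Poisson (CSR), Thomas (clustered),
  Matérn hard-core (regular) and growth–dispersal point patterns,
  FISH-like images with known cell/particle ground truth, two-regime
  power-law rheology curves with a known yield stress, and Dirichlet
  abundance tables — so every stage of the pipeline is testable without
  any external data.

## Worked example

```r
library(lumispat)

# a clustered pattern at image scale, and its H function
w   <- spat_window(0, 200, 0, 200)                       # um
pats <- lapply(1:6, function(i) gen_thomas_pattern(
  parent_intensity = 0.002, mean_offspring = 20,
  offspring_sigma = 2, window = w, seed = i))
sfs <- lapply(pats, function(p) kinhom_border(p, estimate_intensity(p)))
pooled <- pool_and_ci(sfs)
cluster_radius(pooled)
#> [1] 2.7
```

The pooled H curve peaks at r = 5.4 µm, and half that radius, 2.7 µm,
estimates the typical cluster radius — within a factor of two of the
generator's dispersion scale (σ = 2 µm, nominal cluster radius 2σ = 4 µm),
which is the accuracy this readout supports. Comparing those six images
against six CSR patterns:

```r
csr <- lapply(7:12, function(i) {
  p <- gen_poisson_pattern(0.05, w, seed = i)
  kinhom_border(p, estimate_intensity(p))
})
studentized_permutation_test(list(sfs, csr), r_max = 20, n_perm = 999, seed = 1)
#> Studentized permutation test: T = 1.224e+04, p = 0.002 (999 permutations,
#> r in [0, 20] um, groups 6/6)
```

Yield stress from replicate oscillatory measurements, and the depth to
which a 3 cm-amplitude, 1 rad/s contraction can fluidize the content:

```r
s <- summarize_yield(c(47.79, 50.13, 39.66, 36.25, 58.21))
round(c(s$mean_pa, s$sd_pa), 1)
#> [1] 46.4  8.7

mixing_depth(stokes_parameters(amplitude = 0.03, omega = 1))
#> mixing depth D = 0.2056 m (wall stress amplitude 50.17 Pa)
```

A sub-yield contraction (e.g. amplitude 1 cm, wall stress amplitude
16.7 Pa < 45 Pa) returns D = 0: it cannot fluidize the content at all.

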