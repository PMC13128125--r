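---
title: "Methods: quantifying micro-scale bacterial clustering in gut content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying micro-scale bacterial clustering in gut content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lumispat)
```

## The scientific question

Fluorescence in-situ hybridization (FISH) images of fixed gut content show
that bacteria of the same species sit in micrometre-scale clumps rather than
being randomly dispersed. Two competing physical processes plausibly govern
this structure: cell division in a digesta that behaves as a soft solid
below its yield stress (holding daughter cells in place), and gut-wall
contractions strong enough to exceed that yield stress locally, fluidizing
and re-mixing the content. `lumispat` implements the full measurement chain
— image to point pattern, point pattern to spatial statistic, statistic to
group comparison — plus the rheological and fluid-dynamic models that
connect the statistics to the physical mechanism, and a synthetic-data
module that makes every stage testable with known ground truth.

## Cell detection

The detector converts a grayscale image (a maximum-intensity projection of
a confocal stack) into per-cell coordinates in micrometres.

1. **Preprocessing** (`preprocess`). White top-hat filtering with a disk
   structuring element (default radius 2 µm) removes any background
   structure larger than a cell; intensities are then stretched so the
   99.9th percentile maps to full scale. Because the later threshold is
   mean-relative, the pipeline is invariant to affine rescaling of the raw
   intensities — gain and offset of the microscope do not matter.
2. **Segmentation** (`segment`). The binarization threshold is a multiple
   (default 2.0) of the mean filtered intensity — an image-adaptive rule
   that needs no absolute intensity calibration. Foreground pixels are
   labeled as 8-connected components; per-region area, intensity-weighted
   centroid, eccentricity, solidity and axis lengths are computed with
   pixel centres at (i − 0.5)·pixel_size.
3. **Classification** (`classify_regions`). Food particles —
   autofluorescent plant debris — are removed first: area ≥ 20 µm² and
   major/minor axis ratio ≥ 3. Single cells must have area in 0.2–3 µm²,
   eccentricity ≤ 0.95 and solidity ≥ 0.8. Larger non-particle regions are
   cluster candidates; sub-minimum regions are noise. The image source
   prints none of these constants, so they are package defaults tuned on
   synthetic fixtures, exposed in `detection_params()`, and recorded in
   every result.
4. **Cluster splitting** (`split_clusters`). Touching cells are separated
   in up to two passes: Sobel gradient magnitude with non-maximum
   suppression gives thin edge curves; a closing (dilation then erosion,
   default disk radius 1 px) seals gaps; connected components of the
   region minus the closed edge band are core candidates; cores containing
   a local intensity maximum act as markers (this rejects the low-gradient
   outer rim of a blob and the saddle pocket between two cells), and every
   region pixel joins its nearest marker. Sub-regions passing the
   single-cell rule are emitted as cells labeled `from_cluster`;
   an unsplittable blob contributes one intensity-weighted centroid, so no
   cluster region is silently dropped. "Two passes of edge detection and
   dilation/erosion" admits several readings; this marker-based reading is
   the package's interpretation and is deliberately conservative —
   over-splitting would manufacture spurious short-range clustering in the
   downstream statistics, which is worse than occasionally under-splitting.

`match_to_truth` scores detections against a ground-truth pattern by
greedy one-to-one nearest-neighbour matching within a cutoff, reporting
precision, recall and centroid RMSE.

## Inhomogeneous Ripley statistics

Cell density inside an image varies for reasons unrelated to biological
clustering (food particles, tissue folds), so the homogeneous K function
would conflate density gradients with aggregation. The package therefore
uses the intensity-weighted (inhomogeneous) form with border correction:

$$\hat K(r) = \frac{\sum_{i:\, b_i \ge r} \hat\lambda(x_i)^{-1}
  \sum_{j \ne i,\ d_{ij} \le r} \hat\lambda(x_j)^{-1}}
  {\sum_{i:\, b_i \ge r} \hat\lambda(x_i)^{-1}},$$

where $b_i$ is the distance of point $i$ to the window boundary: only
points at least $r$ from the edge act as focal points, eliminating the
deficit of neighbours near the border. No further renormalization is
applied. $L(r)=\sqrt{K(r)/\pi}$ and $H(r)=L(r)-r$ centre the statistic so
that CSR gives $H=0$, clustering $H>0$, regularity $H<0$.

**Intensity estimation.** $\hat\lambda$ at the data points is a
leave-one-out isotropic Gaussian kernel estimate, edge-corrected by
dividing by the kernel mass inside the rectangular window (which
factorizes over x and y). The default bandwidth is 0.15 × the shorter
window side — smooth enough that genuine short-range clustering is not
absorbed into the intensity surface (which would bias H toward zero), yet
flexible enough to track image-scale density gradients. The bandwidth is a
visible knob; estimates are floored at 10⁻¹² µm⁻² so weights stay finite.
Leave-one-out matters: including the point itself inflates $\hat\lambda$
exactly where pairs are counted and biases $\hat K$ down.

**Pooling.** Per-radius numerators and denominators are retained so that
several images pool as a ratio of sums, not a mean of ratios — images with
more eligible focal mass properly dominate. The confidence band is the
pointwise mean of per-image H curves ± $t_{n-1,0.975}$ × SE; with six
images per condition this matches the small-sample uncertainty honestly.

**Cluster radius.** The radius maximizing pooled H approximates the
cluster *diameter* within about a factor of two, so
`cluster_radius` returns argmax$_r$ H / 2, ties toward the smaller radius,
and `NA` when H never rises above zero (no clustering to size).

**Group comparison.** Whether two sets of images differ is tested with the
Studentized permutation test for groups of functional summaries:
$$T=\sum_{i<j}\int_0^{20\,\mu m}
 \frac{(\bar H_i - \bar H_j)^2}{s_i^2/m_i + s_j^2/m_j}\,dr,$$
integrated by the trapezoid rule on the default grid (201 radii, 0–20 µm,
0.1 µm step), with whole images permuted across groups (sizes preserved)
and the add-one p-value $(1+\#\{T^*\ge T\})/(1+n_{perm})$, so p can never
be zero and is valid at any permutation count. The statistic is applied to
H curves; H is a deterministic transform of K, and studentization makes T
invariant to rescaling, so this choice only affects how radii are weighted
relative to the K-scale version. Testing one condition against CSR
(`test_against_csr`) simulates a matched Poisson group — same windows,
intensities fitted per image — and runs the same two-group test; this
reconstruction is a package choice, since a one-group-versus-CSR recipe is
not uniquely determined by the permutation framework.

## Community divergence

Relative-abundance profiles are compared with the Jensen-Shannon
divergence, $JSD(P,Q)=\tfrac12 D_{KL}(P\|M)+\tfrac12 D_{KL}(Q\|M)$ with
$M=(P+Q)/2$ and the convention $0\log 0=0$; it is symmetric and bounded by
$\log 2$. Natural logarithms are the default (base 2 available); absent
taxa are outer-joined as zeros. `grouped_comparison` aggregates a pairwise
JSD matrix into base/base, tip/tip and base/tip groups and runs one-sided
Mann-Whitney U tests between them; the tested direction is a **required**
argument because the biological hypothesis (e.g. "cross-site distances
exceed within-site distances") fixes the tail, and a silent default would
invite accidental two-sided reasoning. The U test is exact for group sizes
up to 20 without ties, normal-approximated with tie correction otherwise;
all-tied inputs return p = 1 (no evidence) rather than a division by a
zero variance.

## Rheology

Amplitude sweeps (strain 0.1–1000% at ω = 1 rad/s) show two power-law
regimes of stress versus strain. `yield_from_intersection` fits
$\log\sigma$ on $\log\gamma$ in a below-yield and an above-yield region
and intersects the fits; the default regions are strains below half the
G′/G″ crossover strain (the solid-like regime, safely below yield) and the
top decade of strain (fully yielded). The measurement protocol does not
prescribe fit windows, so both limits are arguments and are stored in the
estimate. Degenerate geometry (below-exponent ≤ above-exponent, i.e. no
flattening) is an error, not a number. The estimator is exactly
scale-equivariant in stress.

`find_crossover` locates the G′/G″ crossover at the first sign change of
G′ − G″ by log-log interpolation — both moduli are near power laws, so
interpolation in log space is exact for power-law data.

`yield_from_creep` fits a line to the last half of each creep-compliance
record. A curve is fluidized when its tail slope exceeds a threshold *and*
the tail is genuinely linear (R² ≥ 0.98); the yield stress is the lowest
fluidized applied stress. The fluidization criterion in the protocol is
qualitative ("compliance increases linearly with time"), so the package
must pick a quantitative rule: a naive "10 × the median pre-yield slope"
is circular (pre-yield membership is what is being decided), so the
default threshold is 10 × the median absolute tail slope among curves
*failing* the linearity screen, and zero when every curve passes it — this
keeps the all-fluidized boundary case returning the lowest applied stress.

`summarize_yield` reports mean ± sample SD (n − 1), the convention used
for replicate yield measurements.

## Contraction-mixing model

Gut-wall contractions are modeled as Stokes' second problem: a rigid plane
at y = 0 oscillating in-plane with velocity $A\omega\cos\omega t$ beneath
a semi-infinite Newtonian fluid of viscosity μ and density ρ:

$$u(y,t)=A\omega e^{-ky}\cos(\omega t-ky),\qquad
\tau(y,t)=A\omega\sqrt{\rho\omega\mu}\,e^{-ky}\sin(\omega t-ky-\pi/4),$$

with $k=\sqrt{\omega/2\nu}$, $\nu=\mu/\rho$. The Newtonian approximation
is retained deliberately — the model estimates orders of magnitude, and a
shear-thinning constitutive law would add parameters the data cannot fix.
Matching the stress amplitude to the digesta's yield stress gives the
mixing depth $D=-\sqrt{2\nu/\omega}\,\ln[\tau_{yield}/(A\omega\sqrt{\rho\omega\mu})]$.
When even the wall amplitude is below yield the formula's negative D is
unphysical; `mixing_depth` returns D = 0 with `attained = FALSE` instead.
Defaults are the measured digesta values: μ = 2237 Pa·s, ρ = 1250 kg/m³
(mean of replicate measurements 1.16, 1.29, 1.31 g/ml to three significant
figures), τ_yield = 45 Pa. Replicate yield estimates span roughly 20–60 Pa
depending on method (oscillatory intersection 46.4 ± 8.7 Pa, creep 35 ±
13.2 Pa), so τ_yield is everywhere an explicit parameter rather than a
hidden constant; results should be read as order-of-magnitude. The
amplitude/frequency grids for depth maps are user-supplied; illustrative
ranges (A = 2–4 cm, ω = 0.5–2 rad/s) produce centimetre-to-decimetre
depths. Everything is SI internally; `um_to_m` and friends convert the
imaging-scale units.

## Synthetic data: what it emulates and what it does not

The generators define the package's test conditions:

* `gen_poisson_pattern` (CSR null), `gen_thomas_pattern` (clustered, with
  closed-form $K(r)=\pi r^2+\kappa^{-1}(1-e^{-r^2/4\sigma^2})$ used as an
  analytic oracle; parents are simulated in a window expanded by 4σ to
  avoid edge deficit), and `gen_hardcore_pattern` (Matérn type-II
  regularity) span the three qualitative pattern classes.
* `gen_growth_dispersal_pattern` is a minimal mechanistic simulator of the
  proposed clustering mechanism — synchronous doubling with Gaussian
  division jitter, and periodic lineage-level scattering with a
  configurable probability. The mechanism is hypothesized, not measured;
  the rules here are the package's own invention, configurable, and
  non-canonical.
* `render_image` draws cells as Gaussian blobs of scale cell_radius/2 (so
  ~95% of mass lies within the nominal radius), food particles as bright
  rotated rectangles sized to exceed the detector's removal rule (so truth
  and filter agree by construction) and placed clear of cells by rejection
  sampling, plus additive Gaussian noise. The default field emulates a
  184.5 µm window at 2048 px (0.09 µm/px). Stated as side lengths: the
  imaging protocol quotes field "areas" of 184.5 and ~255 µm² that are
  inconsistent with a 2048-pixel field of view unless read as side
  lengths in µm, which is how the package reads them.
* `gen_rheology_dataset` produces two-regime power-law sweeps continuous
  at the yield point, moduli crossing by default at twice the yield strain
  (where the solid-to-liquid transition sits in yield-stress materials),
  and creep curves that gain a late-time linear term exactly at and above
  the true yield stress.
* `gen_abundance_table` draws Dirichlet-distributed compositions around
  per-site means — the simplest compositional noise model with one
  precision knob.

What passing tests on these data do **not** show: performance on real
images with deconvolution artefacts, intensity inhomogeneity from tissue,
out-of-focus light, or touching cells at arbitrary density; real rheometer
artefacts (wall slip, inertia, drying); or sequencing noise beyond
Dirichlet compositional scatter. The synthetic suite validates the
*estimators*, not the instruments.

## Numerical choices and problem sizes

* Radius grid 0–20 µm in 0.1 µm steps (201 points); radii are limited to
  half the shorter window side, where the border correction retains focal
  points.
* The K estimator accumulates per-radius sums by difference arrays over
  the pair list (O(pairs + radii)) and was verified against a brute-force
  double loop to 10⁻¹⁰; distances use a BLAS-based squared-distance
  matrix.
* Radii with no eligible focal point are `NA` and propagate; an empty
  pattern yields an all-`NA` summary with a warning.
* Generators are reproducible bit-for-bit for a fixed seed (each takes a
  `seed` argument and restores the caller's RNG state afterwards).
* Calibration sizes used by the test-suite and acceptance script, chosen
  to bound Monte Carlo error while keeping a full run in the minutes
  range: CSR calibration 100 seeds × 6 images of ~2000 points
  (200 × 200 µm, λ = 0.05 µm⁻²); Thomas oracle 200 replicates;
  permutation-test size 200 trials × 12 images of ~500 points with 199
  permutations; detection round trip 100 images at 0.18 µm/px (a 2×
  downsampled field, where a 1-px RMSE bound is the stricter test of the
  two resolutions we render); yield recovery 50 noisy sweeps.
* Band-coverage assertions ("mean curve inside the pointwise 95%
  Monte-Carlo band") require ≥ 95% of radii inside the band: demanding
  every one of 201 correlated radii would fail ~5% of the time for a
  correct estimator.

## Known limitations

* Only rectangular observation windows and the border correction are
  implemented; isotropic/translation corrections and non-rectangular
  masks are out of scope.
* The detector handles 2-D projections only (no z-stacks, no spectral
  unmixing) and its morphological defaults are tuned on synthetic blobs —
  real data will need parameter review against a few annotated images.
* The intensity-estimation defaults (Gaussian kernel, bandwidth
  0.15 × short side) are a package choice; other reasonable defaults move
  H by small amounts near r = 0, which is why the CSR calibration keeps a
  ±0.5 µm tolerance band.
* Frequency-sweep rheology data are parsed but no statistic is defined on
  them; the mixing-depth model ignores gut geometry (curvature, lumen
  closure) and peristaltic transport.
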