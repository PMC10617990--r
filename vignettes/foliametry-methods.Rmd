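---
title: "Folial morphometry and phylogenetic comparative analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folial morphometry and phylogenetic comparative analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foliametry)
```

# What the package computes

`foliametry` measures cerebellar folding from 2D histological sections and
places those measurements in an explicit evolutionary context. It has three
layers:

1. **Contour morphometry.** From a manually segmented, scale-calibrated pial
   contour it computes section area and length, a multiscale curvature
   signature, a gyrus/sulcus/wall classification of contour vertices, and
   per-folium width (chord between flanking sulci) and perimeter (arc
   between them), summarised by medians. A gyrification index (contour
   length over convex-hull length) is reported for comparison; unlike the
   folial measures it cannot distinguish many shallow folds from few deep
   ones.
2. **Molecular-layer thickness.** From a section image and its contour it
   estimates the thickness of the bright outer molecular layer by tracing
   profile lines from every contour vertex down the gradient of a relaxed
   Laplacian potential, sampling grey values along each line, locating the
   bright-to-dark boundary at the most negative grey gradient, and taking
   the median across lines.
3. **Comparative statistics.** Species-by-trait tables (log10 units) and an
   ultrametric phylogeny feed maximum-likelihood fits of three multivariate
   trait-evolution models — Brownian motion (BM), Ornstein–Uhlenbeck (OU)
   and early burst (EB) — ranked by AICc; the winning model's species
   covariance structure then conditions the evolutionary covariance,
   partial correlations with edge-exclusion tests, phylogenetic PCA,
   bivariate and multivariate allometry, and ancestral state estimation.

Everything is exercised end to end by seeded synthetic generators, so the
whole pipeline is testable without any external image or tree.

# The evolutionary models

All three models are Gaussian on the tree. Writing $t_{ij}$ for the shared
root-to-MRCA path length of tips $i$ and $j$ on an ultrametric tree of depth
$T$, and $R = \sigma\sigma^\top$ for the $m \times m$ trait rate matrix, the
covariance between trait $k$ of tip $i$ and trait $l$ of tip $j$ is

* **BM**: $R_{kl}\, t_{ij}$, mean = root state;
* **EB**: $R_{kl}\, (e^{r t_{ij}} - 1)/r$ with rate $r \le 0$ (the
  $r \to 0$ limit is exactly BM), mean = root state;
* **OU** (diagonal attraction $\alpha$, stationary root):
  $\dfrac{R_{kl}}{\alpha_k + \alpha_l}
   \exp\{-(\alpha_k + \alpha_l)(T - t_{ij})\}$, mean = optimum $\theta$.

The OU implementation offers two root conventions. The default
(`ou_root = "stationary"`) draws the root from the stationary distribution,
the standard identifiable choice on ultrametric trees; its covariance
*diverges* as $\alpha \to 0$, so the BM reduction cannot be checked there.
The alternative (`ou_root = "fixed"`) clamps the root at $\theta$, giving
covariance
$\frac{R_{kl}}{\alpha_k+\alpha_l} e^{-(\alpha_k+\alpha_l)(T - t_{ij})}
 (1 - e^{-(\alpha_k+\alpha_l) t_{ij}})$,
which reduces to BM entrywise as $\alpha \to 0$ (the leading deviation is
$O(\alpha T^2)$, which is why the reduction tests run on unit-depth trees).
Both forms are exact; the reduction chain EB($r{=}0$) $\equiv$ BM and
OU($\alpha \to 0$, fixed root) $\to$ BM is verified to $10^{-6}$.

**Fitting.** BM and EB have matrix-normal structure: given the (for EB,
transformed) species covariance, the per-trait root and the full rate matrix
have closed-form maximum-likelihood solutions, so BM is non-iterative and EB
needs only a one-dimensional search over $r \in [-30/T, 0]$. The
diagonal-$\alpha$ OU is fitted by L-BFGS-B over $\log\alpha$ and the
log-Cholesky factor of $R$ with the optima $\theta$ profiled out by GLS and
an analytic gradient (the derivative of the profiled log-likelihood with
respect to each covariance block). Restarts jitter the moment-matched
starting point ($\alpha_0 = \log 2 / (T/2)$, $R_0$ from the sample
covariance scaled through the stationary relation). Convergence tolerance is
`factr = 1e7` (about $10^{-9}$ relative on the log-likelihood); parameter
bounds are $\alpha \in [10^{-8}, 10^3]$.

**AICc.** $\mathrm{AIC} = -2\ell + 2p$ and
$\mathrm{AICc} = \mathrm{AIC} + (2p^2+2p)/(n-p-1)$. Free parameters: BM
$m + m(m+1)/2$, OU $2m + m(m+1)/2$, EB $m + m(m+1)/2 + 1$. The sample size
$n$ is ambiguous for matrix-variate data; the package defaults to the total
number of scalar observations (species × traits, `aicc_n = "cells"`), with
`"species"` available. Exact AICc ties rank alphabetically by model name.

**Model-selection power.** `model_selection_power()` draws a random trait
correlation matrix per replicate (Wishart with $2m$ degrees of freedom,
normalised to unit diagonal), simulates BM tips on a seeded 56-tip
pure-birth tree of depth 180 My, fits BM and diagonal-$\alpha$ OU, and
counts AICc selections. Because the OU adds $m$ attraction parameters, the
AICc penalty (~23 at $m = 9$, $n = 504$ cells) dominates the boundary
likelihood gain under BM truth, and BM is selected in ≈99–100% of
replicates. The default 200 replicates keep the simulation to a few
minutes; a single optimisation start per replicate is used there, which can
only understate the OU likelihood and therefore biases, if at all, toward
the model the penalty already disfavours being selected less often — the
estimate is insensitive to this in practice.

# Comparative statistics under the selected model

The species structure $C$ is $t_{ij}$ for BM, the EB transform for EB, and
$\exp\{-2\bar\alpha(T - t_{ij})\}$ for OU, with $\bar\alpha$ the mean of the
fitted per-trait attractions (one shared structure is required for GLS; the
averaging choice is recorded in the fit metadata). The GLS mean and
covariance are
$\hat\mu = (\mathbf{1}^\top C^{-1}\mathbf{1})^{-1}\mathbf{1}^\top C^{-1} X$
and $\hat R = (X - \mathbf{1}\hat\mu)^\top C^{-1} (X - \mathbf{1}\hat\mu) /
(n-1)$. Partial correlations come from the precision matrix
$\Omega = \hat R^{-1}$ as $-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$; each
pair is tested by the edge-exclusion deviance $-n\log(1 - \rho_{ij}^2)$
against $\chi^2_1$ with $n$ = number of species. No multiple-testing
correction is applied to the pairwise p-values, but a Holm-adjusted column
is always reported alongside. Note the finite-sample floor of the null
$|\rho_{ij}|$ is $\sqrt{2/\pi}/\sqrt{n - m}$ (≈0.11 at $n=56$) — small
observed partials at this scale carry no signal.

Phylogenetic PCA eigen-decomposes $\hat R$; scores project the deviations
from the GLS mean; signs are fixed so each component's largest-magnitude
loading is positive. Multivariate allometric slopes are ratios of PC1
loadings; bivariate allometry reports the GLS regression slope (analytic
t-interval) and the orthogonal slope from the leading eigenvector of the
2×2 $\hat R$ (seeded parametric-bootstrap interval, 1000 draws by default).

Ancestral states are estimated for scalar characters (typically PC scores):
tips and internal nodes are jointly Gaussian under the fitted model's node
covariance (shared path lengths for BM/EB; exponential in tree distance for
stationary OU), the estimate is the conditional mean of the internal nodes
given the tips, and the conditional variance includes the universal-kriging
term for the estimated GLS mean — without it, nominal 95% intervals cover
only ~92% in simulation; with it, coverage is on target.

`partial_correlation_power()` builds a precision matrix with unit diagonal,
the target partial correlation on the (1,2) pair and a small nuisance value
(default 0.05) elsewhere, inverts and normalises it to a trait correlation,
simulates matrix-normal tips under the species structure, and reports the
edge-exclusion rejection rate per level.

# Contour morphometry choices

* **Resampling** is uniform in arc length; the default spacing of 0.05 mm
  gives ≥20 vertices on a ~1 mm folium. The vertex count is rounded so the
  spacing is exactly uniform; halving it changes folial medians by <2%.
* **Curvature** is the central-difference estimator on the uniformly
  resampled chain, in 1/mm, positive on convex arcs of a counter-clockwise
  contour. It matches $1/R$ on circles and closed-form ellipse curvature to
  1% when the input polyline sampling is a few times finer than the output
  spacing.
* **The 10 signature scales** form a geometric progression from 0.5% to 16%
  of the contour perimeter — folium-scale to lobule-scale — and are
  configurable. Smoothing is circular Gaussian convolution via FFT with a
  sum-normalised kernel, so the circular mean of curvature is conserved
  exactly and a single harmonic $\cos(ks)$ is attenuated by
  $e^{-(\sigma k)^2/2}$.
* **Classification.** The deterministic rule thresholds the median-centred
  signature at the scale with the largest MAD at $\pm\tau$,
  $\tau = \max(0.25\,\mathrm{MAD},\ 0.05 \cdot 2\pi/P)$; the floor (5% of
  the contour's mean turning curvature $2\pi/P$) keeps convex contours free
  of spurious sulci. A fixed mid-scale column fails at high fold counts,
  where heavy smoothing buries the folding signal; the adaptive column does
  not. The random-forest mode is trained once per session on 200 seeded
  rosette fixtures (fold counts 4–20, relative amplitudes 0.03–0.2, radial
  noise to 5% of amplitude, 0–1 nesting levels) labelled by the generator's
  ground truth, on median-centred, MAD-scaled signature columns (features
  invariant to contour size and baseline curvature). On noise-free rosettes
  it agrees with the ground-truth labels on ≥95% of vertices.
* **Folia.** Each maximal circular sulcus run contributes one anchor (most
  negative smoothed curvature, ties to the lowest index); consecutive
  anchors enclosing at least one gyrus vertex bound a folium; anchor arcs
  without an interior gyrus vertex are merged into the following arc to
  avoid double-counting slivers. Width ≤ perimeter holds by construction
  (chord ≤ arc).
* **Envelope for the gyrification index**: the convex-hull perimeter —
  parameter-free and reproducible; alternatives (morphological closing)
  are deliberately out of scope, and the index is reported for context
  only.

# Thickness estimation choices

* **Preprocessing**: luminance conversion, 3×3 median filter, global
  rank-based histogram equalisation to [0, 1] (a flat image is returned
  unchanged). Grey profiles are sampled from the equalised image; the
  estimate is invariant under affine grey rescaling of the input by
  construction.
* **Potential**: red-black SOR relaxation of the masked image with the
  contour-adjacent ring fixed at its (bright) surface values and, by
  default, sub-Otsu-threshold mask pixels held as interior dark anchors.
  The anchors make the relaxed field decrease monotonically from surface
  to granular layer and let the relaxation converge quickly on the thin
  bright band; without them, plain partial diffusion leaves a flat plateau
  mid-band on thick molecular layers and the per-vertex descent lengths
  collapse. The generic solver (`laplace_relax`) takes arbitrary
  free/fixed sets and reproduces the closed-form log-radial harmonic on an
  annulus to 2%.
* **Streamlines** start at each contour vertex, step 0.5 px down the
  bilinear-interpolated negative gradient while the potential decreases
  (the exterior is assigned a potential above all surface values so the
  first step always enters the tissue), and continue straight after a
  local minimum. All lines share one sample count: the 95th percentile of
  per-vertex descent lengths, capped at 2 mm of tissue. Halving the step
  changes the estimate by <1%; doubling the raster resolution by <2%.
* **Boundary**: profiles are smoothed with a 3-sample moving average and
  differenced; the boundary is the most negative difference below a
  prominence of 0.05 grey units, refined to the sharpest unsmoothed
  difference inside the smoothing window (ties to the surface side), so an
  ideal step edge is localised exactly. Profiles without a prominent drop
  are invalid; the section estimate is the median over valid profiles
  (≥10 required) with IQR and the invalid fraction, and is unchanged when
  10% of profiles are invalidated.
* **Resolution QC**: mask pixels per mm² of section area against an opaque
  threshold (default 3.5, on the scale of the source collection's plot),
  applied inclusively; failing sections keep area/length but skip
  thickness.

# What the generators emulate — and what they do not

`generate_folded_contour` draws
$\rho(\varphi) = R + a\cos(k\varphi)$ with optional nested harmonics at
$3k, 9k, \dots$ (amplitude divided by 3 per level) and smooth periodic
radial noise, sampled uniformly in arc length, with ground-truth vertex
labels (±15% of the fold period around each radial extremum) and exact
chord/arc folium geometry from dense quadrature. `generate_layered_section_image`
rasterises a bright molecular band of known constant thickness over a dark
granular band with Gaussian blur and pixel noise. `generate_tree` is a
rescaled Yule tree; `simulate_traits` draws tips from the exact model
multivariate normal (verified against the analytic covariance at $10^4$
replicates within 3.5 Monte-Carlo standard errors — the widening from 3
keeps the family-wise error of testing all covariance entries
simultaneously at the percent level).

The fixtures deliberately do **not** mimic staining artefacts, tears, slice
deformation, per-vertex thickness variation, uneven illumination, or the
anisotropic fold geometry of real sections. Passing the recovery tests
therefore shows the algorithms are correct on well-posed inputs with known
truth; it does not certify accuracy on degraded historical material, where
segmentation quality and resolution dominate.

# Problem sizes

The test suite and the acceptance script run, by design, at desk scale: the
model-selection simulation uses 200 replicates of 9 traits on one 56-tip
tree; parameter recovery uses 100 replicates of 2 traits at 56 tips;
thickness recovery uses ~400-pixel-wide rasters at 0.01 mm/px with bands of
0.1–0.5 mm; the synthetic study defaults to 12 species (6 in the tests).
These sizes were chosen so each suite completes in minutes on one CPU while
keeping every statistical tolerance meaningful.

# Known limitations

* OU fitting uses diagonal attraction; full $\alpha$ matrices are weakly
  identifiable at ~56 species and are not attempted.
* One species structure $C$ is shared across traits for the GLS statistics;
  with heterogeneous fitted $\alpha$ this is an approximation (mean
  $\bar\alpha$).
* The gyrification envelope is the convex hull; concave "closing"
  envelopes would give systematically different (larger) indices.
* Thickness profiles can cross into the opposite bank of a very narrow
  sulcus if the profile-length cap exceeds the folial half-width; the
  descent-length rule and the 2 mm cap protect typical geometries.
* The edge-exclusion test is asymptotic; at $n \approx 56$ its size is
  ~0.05–0.07 depending on the number of conditioned traits.
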