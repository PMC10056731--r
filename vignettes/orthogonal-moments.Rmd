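---
title: "Orthogonal image moments: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal image moments: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthim)
```

## The model

An image moment is the projection of an intensity field $f(x,y)$ onto a
kernel $h_{pq}$,
$$M_{pq} = \iint_D h_{pq}(x,y)\, f(x,y)\, dx\, dy .$$
When the kernels are orthogonal on $D$ the moment set is non-redundant and
the expansion inverts term by term, which is what makes truncated moment
vectors useful descriptors: the first few coefficients carry the bulk of the
image's low-frequency structure, and reconstruction error decreases as more
are added.

Two domain geometries are implemented.  **Cartesian** families live on the
square (Legendre on $[-1,1]^2$) or the pixel lattice (discrete Chebyshev
moments of both kinds); their kernels are separable products
$h_{pq}(x,y) = h_p(x)h_q(y)$.  **Circular** families live on the unit disk
with kernels $R_n(r)\,e^{im\theta}$; because a rotation by $\phi$ multiplies
$M(n,m)$ by the unit-modulus phase $e^{-im\phi}$, the moduli $|M(n,m)|$ are
rotation invariants — the feature vectors exported by `magnitudes()`.

Within the circular group the families differ in their radial sets: Jacobi
polynomials (Zernike, pseudo-Zernike, orthogonal Fourier–Mellin,
Chebyshev–Fourier, Jacobi–Fourier and its pseudo variant), harmonic
functions (radial harmonic Fourier, exponent Fourier, and the polar
complex-exponential/cosine/sine transforms), and eigenfunctions
(Bessel–Fourier, $J_\nu(\lambda_n r)$ at the positive roots $\lambda_n$ of
$J_\nu$).  A fractional-order variant of a family substitutes
$r \leftarrow r^\alpha$ and folds the Jacobian weight
$\alpha r^{2\alpha-2}$ into the kernel, so orthogonality on the disk is
preserved and $\alpha = 1$ recovers the integer-order family exactly
(`fractional_substitution()`).

Every radial set in the package is normalized to be **orthonormal on
$[0,1]$ with weight $r$**, and the full 2-D basis carries a further
$1/\sqrt{2\pi}$.  This single normalization convention means moments,
magnitudes and reconstruction share one code path for all seventeen
circular families, and the constant image $f \equiv 1$ reproduces itself
under reconstruct-after-project for each of them.

## Discretization conventions

These choices are not dictated by the underlying theory and are therefore
fixed, documented, and tested here:

* **Pixel centers, midpoint rule.** Pixel $(i,j)$ (0-based) maps to
  $x_j = (2j - W + 1)/W$, $y_i = (2i - H + 1)/H$; the double integral is the
  midpoint sum with cell area $\Delta = 4/(HW)$.  Quadrature error is
  $O(h^2)$; the test suite asserts this signature rather than pretending the
  sums are exact (e.g. the higher Legendre moments of a constant image
  shrink fourfold when the grid doubles).
* **Inscribed disk.** The unit disk is inscribed in the image square and
  pixels with $r > 1$ are excluded from all circular sums.  This keeps the
  basis orthogonal on its native domain at the cost of ignoring the
  corners (about $1 - \pi/4 \approx 21\%$ of pixels).
* **Counter-clockwise angles.** Rows are stored top-to-bottom, so the
  storage y-axis is flipped before computing $\theta = \mathrm{atan2}(y,x)$.
  The exact 90°-rotation invariance tests depend on this convention.
* **Singular kernels.** The RHFM, EFM and Chebyshev–Fourier radial factors
  behave like $r^{-1/2}$ or $r^{-1/4}$ at the origin; the kernel value at an
  exact center pixel (odd-sized grids) is set to 0.  The singular point has
  measure zero, so the moments converge as the grid refines, but these
  families do show the slowest discrete-orthogonality convergence (the
  Chebyshev–Fourier Gram off-diagonal is the largest of all families at
  $256^2$, about $3\times 10^{-2}$, still under the 0.05 acceptance bound).
* **Enumeration order.** Indices are emitted with $n$ ascending, then $m$
  ascending, so feature vectors are bit-stable across runs.  Both signs of
  $m$ are kept even though $|M(n,-m)| = |M(n,m)|$ for real images with
  real radial kernels: the published feature counts (Zernike 21,
  pseudo-Zernike 36, EFM 121, PST 55, the rest 66) count signed
  repetitions, and the duplication is harmless to the classifiers.  For the
  two complex-radial families (EFM, PCET) conjugation pairs $(n,m)$ with
  $(-n,-m)$ instead, so the signed set is not redundant there.

## Tunable parameters

* `n_max`, `m_max` (default 5): the benchmark order.  The Cartesian index
  set is triangular, $p + q \le 5$, giving 21 features for the discrete
  Chebyshev families; Legendre uses the bound $n_{\max}+1 = 6$ because the
  reference feature count for LM is 28, which is only consistent with a
  triangular set at bound 6.  Both readings are available via `n_max`.
* `alpha` (default 1.5 for `Fr*` families, 1 otherwise): the fractional
  order.  The benchmark protocol this package mirrors does not state its
  $\alpha$, so 1.5 — a mild, commonly used strengthening of the radial
  resolution near the rim — was chosen once and is recorded in every output
  sidecar.
* `jacobi_p, jacobi_q` (default 3, 2): the free Jacobi–Fourier parameters,
  chosen distinct from the specializations that reproduce OFMM
  ($p=q=2$) and PJFM ($p=4, q=3$) so JFM is a genuinely different
  descriptor.  Constraint $p > q > 0$.
* `bessel_nu` (default 1): Bessel order for BFM; roots are found by
  bracketed root-finding to 1e-12 and cached.
* GLCM quantization `L` (default 8): the protocol is silent on gray-level
  count; 8 is the common default for Haralick features on 8-bit data.
* LBP threshold: neighbour $\ge$ center, the standard convention; it
  determines that a flat patch maps to the all-ones code (class 255).

## The second-kind Chebyshev construction

"Discrete Chebyshev moments of the second kind" are under-specified in the
literature this package follows.  Two properties were required: discrete
orthonormality on the lattice, and exact reconstruction of polynomial
images of in-range degree (the invariant that makes the discrete families
attractive).  A basis of the form $\sqrt{w}\times\text{polynomial}$
satisfies the first but provably not the second, so the package uses the
weighted-orthogonality construction: polynomials $\pi_n$ orthonormal under
the discrete second-kind weight $w(t) = \sqrt{1-t^2}$ at pixel-center
nodes, with the weight carried by the analysis kernel
($\sqrt{w}\,Q_n$, `chebyshev2_polynomial()`) and the bare polynomials used
in synthesis.  Analysis and synthesis are biorthogonal, so both required
properties hold exactly; the acceptance suite checks the degree-5 round
trip at machine precision.

## Texture baselines

The GLCM is accumulated symmetrically at distance $d = 1$ for the four
standard angles and normalized to sum 1; thirteen Haralick statistics are
computed per angle in a fixed order (energy, contrast, correlation,
variance, inverse difference moment, sum average/variance/entropy, entropy,
difference variance/entropy, two information measures of correlation;
natural logarithm, $0\log 0 = 0$).  The exported descriptor concatenates
all four angle blocks into 52 values — the reference protocol's "thirteen
rotation-invariant features" and its printed size of 52 are in tension, and
the 52-length angle-major reading is adopted; a 90° rotation permutes the
blocks ($0°\!\leftrightarrow\!90°$, $45°\!\leftrightarrow\!135°$), which
order-insensitive learners absorb.  The LBP descriptor thresholds the 8
radius-1 neighbours (diagonals bilinearly interpolated) and maps each code
to the minimum over its circular bit-rotations; a brute-force necklace
count over all 256 patterns confirms the 36 equivalence classes.

## The evaluation protocol

`run_benchmark()` reproduces the standard patch-classification protocol:
stratified 10-fold cross-validation (plain k-fold is ill-posed when a class
has 2 members and $k = 10$, so stratification is used and the small class
lands in exactly 2 distinct folds); per-feature z-scoring fitted on the
training fold only; grid-search model selection by stratified **3-fold
inner** cross-validation inside the training fold (the source protocol does
not describe its selection split; an inner split is the conservative,
leak-free choice); scoring by Eq.-style weighted per-class accuracy — each
class collapsed one-vs-rest to $(TP+TN)/(TP+FP+TN+FN)$ and averaged with
class-support weights, validated against a brute-force oracle on 1000
random confusion matrices.  All randomness flows from one seed; identical
invocations give byte-identical feature CSVs and result tables.

Five classifier categories ship in-package because no classifier library is
available in the target environment: exact k-NN (euclidean/cityblock,
distance-based tie-break), Gaussian naive Bayes with variance smoothing,
CART with Gini impurity, bagged CART, and a **least-squares kernel SVM**
(one-vs-rest, $(K + I/C)\,a = y$ with linear/RBF kernels and the
`scale`-heuristic RBF width).  The LS-SVM replaces the hinge-loss SVM of
the original protocol — it optimizes a squared rather than hinge loss, so
selected hyperparameters and margins are not comparable to libsvm's, but it
occupies the same "numerical function model" category and exposes the same
grid shape.  Grids are deliberately small and enumerated in a fixed order;
ties go to the first occurrence.

## What the synthetic generator does and does not establish

`generate_dataset()` emulates the *shape* of the benchmark tasks — small
single-channel patches (default 64×64 to keep test runtime desk-scale;
61×61 up to 512×512 are supported), a few well-separated texture classes,
per-image random phase so class members differ — with three texture models
chosen to probe different descriptor strengths: oriented gratings (angular
content, circular moments), Gaussian random fields of varying correlation
length (autocorrelation, GLCM), and Gaussian blob mixtures (low-order
shape, Cartesian moments).  Default noise is additive Gaussian with
$\sigma = 0.05$ on a unit intensity scale, enough to make patches
non-trivial but far below class separation.

A green end-to-end test therefore establishes that the pipeline is wired
correctly and that the descriptors separate textures they are designed to
separate.  It does **not** establish clinical performance: the generator has
no anatomy, no scanner physics, no CT/MR noise model, and its classes are
far cleaner than pathology classes.  The published accuracy tables on the
four public medical data sets are out of scope for this build (they require
external downloads), which is why acceptance pins the data-independent
structural constants — the feature-vector sizes — and property suites
instead.

## Numerical notes and degenerate inputs

* Discrete near-orthogonality bound: at $256^2$ every circular family's
  normalized Gram off-diagonal is below $5\times10^{-2}$; the discrete
  Cartesian families are orthonormal to $10^{-10}$ (exactly, by QR).
* Reconstruction-error monotonicity is a continuum property; on a fixed
  grid the quadrature-noise floor can break it once a fixture is fully
  captured.  The monotonicity fixture therefore carries radial content
  through order ~10 (`0.5 + 0.18cos(12r) + 0.17sin(9r^2)`), and the sweep
  runs at $256^2$.
* 30°-rotation invariance is measured as mean absolute magnitude deviation
  relative to the mean magnitude; per-entry relative deviation is
  meaningless for the many near-zero magnitudes of a smooth image.
* Zero-variance features pass through normalization centered but
  undivided; single-class datasets, empty grids, empty class folders,
  non-square inputs to `rotated_pair()`, $k$ beyond the sample count, and
  unknown families/classifiers all raise immediate, specific errors.
* Factorial-form radial polynomials (Zernike, pseudo-Zernike) are exact at
  the benchmark orders; they would overflow around $n \approx 85$, far
  above sensible moment orders.

## Known limitations

PNG and plain-text PGM are the only image formats (no TIFF/BMP/DICOM);
color information is discarded by luminance conversion; no sub-pixel
quadrature or polar-pixel tiling; no scale/translation invariants beyond
the disk normalization; the LS-SVM caveat above; and the synthetic
benchmark ceiling discussed above.
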