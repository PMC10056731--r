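# orthim — orthogonal image moments and texture descriptors

Compact, interpretable descriptors for grayscale images — CT/MR-style
texture patches in particular — built from **orthogonal image moments**: the
projections

```
M_pq = ∬_D  h_pq(x, y) f(x, y) dx dy
```

of an image `f` onto an orthogonal kernel family `h_pq`.  Orthogonality
makes the representation non-redundant and directly invertible, and for the
circular families `h_nm(r, θ) = R_n(r) e^{imθ}` the moduli `|M(n,m)|` are
rotation invariants.  Descriptors of this kind remain competitive with deep
features on medical classification tasks while using orders of magnitude
fewer values per image.

The package implements, behind one uniform interface:

| group | families | size at order 5 |
|---|---|---|
| Cartesian | Legendre (LM), discrete Chebyshev 1st/2nd kind (CHM, CH2M) | 28 / 21 / 21 |
| circular, Jacobi-polynomial | Zernike (ZM), pseudo-Zernike (PZM), orthogonal Fourier–Mellin (OFMM), Chebyshev–Fourier (CHFM), pseudo Jacobi–Fourier (PJFM), Jacobi–Fourier (JFM) + fractional FrJFM | 21 / 36 / 66 × 5 |
| circular, eigenfunction | Bessel–Fourier (BFM) | 66 |
| circular, harmonic | radial harmonic Fourier (RHFM), exponent Fourier (EFM), polar complex exponential / cosine / sine transforms (PCET, PCT, PST) + fractional Fr* variants | 66–121 |
| texture baselines | rotation-invariant LBP histogram (36 classes), 4-angle GLCM/Haralick (52 values) | 36 / 52 |

plus a benchmarking pipeline (stratified 10-fold cross-validation,
train-fold-only z-scoring, grid-search model selection over SVM / k-NN /
decision-tree / naive-Bayes / bagged-tree classifiers, support-weighted
per-class accuracy), a reproducible synthetic texture-patch generator, and a
CLI.

## Worked example

```r
library(orthim)

# 60 synthetic 64x64 texture patches, 3 grating classes
ds <- generate_dataset(n_classes = 3, n_per_class = 20, size = c(64, 64),
                       family = "oriented_grating", seed = 1)

# Zernike moment magnitudes of one patch at order 5
spec <- moment_spec("ZM", n_max = 5)
fv <- magnitudes(compute_circular_moments(ds$images[[1]], spec))
round(setNames(fv$values[1:6], fv$labels[1:6]), 4)
#>  (n=0,m=0) (n=1,m=-1)  (n=1,m=1) (n=2,m=-2)  (n=2,m=0)  (n=2,m=2)
#>     0.8617     0.0027     0.0027     0.0053     0.0010     0.0053

# the full protocol: 10-fold stratified CV, train-fold normalization,
# grid-searched classifiers, weighted per-class accuracy
res <- run_benchmark(ds, c("CHM", "ZM", "RHFM"), c("kNN", "NB"),
                     k = 10, seed = 42)
res
#> evaluation_result (k = 10, seed = 42)
#>         kNN     NB    AVG
#> CHM  0.8778 0.9556 0.9167
#> ZM   0.9000 0.8889 0.8944
#> RHFM 0.9889 1.0000 0.9944

aggregate_by_category(res)
#>   category      mean sd       min       max n
#> 1       CM 0.9166667  0 0.9166667 0.9166667 1
#> 2       HM 0.9944444  0 0.9944444 0.9944444 1
#> 3       JM 0.8944444  0 0.8944444 0.8944444 1
```

`(n=0,m=0)` is the disk-mean energy of the patch; the near-equal pairs at
`±m` reflect the conjugate symmetry of real images.  In the benchmark table
each cell is the mean over the 10 test folds of the weighted per-class
accuracy; `AVG` averages across classifiers, and the category table mirrors
the usual whisker-plot summary (mean / sd / min / max per descriptor
category).

## Command line

```sh
Rscript -e 'orthim::orthim_cli()' synth    --out data --classes 3 --per-class 20 --size 64 --seed 1
Rscript -e 'orthim::orthim_cli()' extract  --data data --out feats --descriptors ZM,RHFM --order 5
Rscript -e 'orthim::orthim_cli()' evaluate --data data --out results.csv --descriptors ZM,RHFM --classifiers kNN --k 10 --seed 42
Rscript -e 'orthim::orthim_cli()' reconstruct --image data/class1/img0001.png --family ZM --order 10 --out rec.png
```

Feature CSVs carry full-precision values plus a JSON sidecar recording the
exact moment specification (including `alpha` for fractional families) and
seed.  Supported image formats: PNG and plain-text PGM (P2); datasets are
directories of class-named subfolders.

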