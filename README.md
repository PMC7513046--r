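# nssfuse

Multi-modal and multi-focus image fusion in the nonsubsampled
contourlet transform (NSCT) domain, for pairs of co-registered
grayscale (or color) images: two medical modalities showing different
tissue, or two photographs focused at different depths. The output is
a single image that keeps, everywhere, whichever source is locally
more informative.

## Method

Both sources are decomposed with the NSCT — a shift-invariant
multi-scale, multi-direction filter bank whose every band keeps the
image's size, built from two-channel nonsubsampled stages satisfying
the Bezout perfect-reconstruction identity

```
H0(z) G0(z) + H1(z) G1(z) = 1 .
```

The two kinds of bands are fused by different rules:

* **Low-pass bands** are fused by sparse representation. All
  overlapping 8×8 patches of both bands are pooled, clustered jointly
  (k-means), and each cluster contributes the leading PCA eigenvectors
  holding ≥ 95% of its variance (δ = 0.95) to a compact dictionary Φ.
  Each patch pair is jointly coded with simultaneous orthogonal
  matching pursuit (SOMP) on a shared atom support; the code with the
  larger ℓ1 norm wins (**Max-L1** rule), the fused patch is
  `Φ α_F + mean(winner)`, and overlapping patches are averaged.
* **Directional high-pass bands** are fused by the **SML-MAX** rule:
  per pixel, the coefficient with the larger Sum-Modified-Laplacian
  clarity (second-difference activity, squared, summed over a 3×3
  window) is copied verbatim — never blended.

The inverse NSCT of the fused bands is the fused image. Objective
quality metrics (mutual information, the gradient-based QAB/F index,
Yang's structural QY) and deterministic synthetic fixtures
(multi-focus pairs with ground truth, pseudo-multi-modal phantoms) are
included, so the whole pipeline is testable without external data.

## Worked example

```r
library(nssfuse)

# synthetic multi-focus pair: left half of A and right half of B are
# defocused; the sharp scene is known ground truth
pair  <- make_multifocus_pair(size = 256, blur_sigma = 3, seed = 0)
fused <- fuse(pair$a, pair$b, fusion_config())

cat(sprintf("RMSE vs ground truth:  A %.4f   B %.4f   fused %.4f\n",
            rmse(pair$a, pair$gt), rmse(pair$b, pair$gt),
            rmse(fused, pair$gt)))
m <- fusion_metrics(pair$a, pair$b, fused)
cat(sprintf("MI %.3f   QAB/F %.3f   QY %.3f\n", m$mi, m$q_abf, m$q_y))
```

```
RMSE vs ground truth:  A 0.0328   B 0.0321   fused 0.0037
MI 4.214   QAB/F 0.838   QY 0.997
```

The fused image is an order of magnitude closer to the all-in-focus
scene than either source: the SML-MAX rule restores the sharp detail
on both halves, and the sparse low-pass fusion keeps the coarse
radiometry of the locally dominant source. MI is the summed mutual
information between the fused image and each source (bits); QAB/F and
QY are edge-transfer and structural indices in [0, 1] (with the
published sigmoid constants, a perfect fusion scores ≈ 0.97 on QAB/F,
not 1).

A command-line front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nssfuse", package = "nssfuse"))')
$CLI synth multifocus --size 256 --seed 0 -o demo/
$CLI fuse demo/a.png demo/b.png -o demo/fused.png
$CLI metrics demo/a.png demo/b.png demo/fused.png
```

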