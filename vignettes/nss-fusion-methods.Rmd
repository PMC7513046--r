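---
title: "Methods: NSCT-domain image fusion with sparse representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NSCT-domain image fusion with sparse representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nssfuse)
```

## The fusion problem

Two co-registered single-channel images of one scene — two medical
modalities, or two photographs focused at different depths — each carry
part of the information. The goal is a single image that keeps, at every
location, whichever source is locally more informative, without the
ringing ("pseudo-Gibbs") artifacts that shift-variant transforms
introduce near edges.

`nssfuse` fuses in the domain of the **nonsubsampled contourlet
transform** (NSCT): a multi-scale, multi-direction decomposition in
which no band is ever downsampled, so every coefficient band has the
source image's size and the transform is fully shift invariant. The
coarse appearance (low-pass band) and the directional detail (high-pass
bands) are fused by different rules, then the inverse transform yields
the fused image.

## The transform

The multi-scale stage is a two-channel nonsubsampled pyramid: at scale
$j$ the signal is filtered with the analysis pair $(H_0, H_1)$
upsampled à trous by $2^{j-1} I$ — zeros are inserted into the
*filters*, the signal is never resampled. Each high-pass band is then
split into $2^k$ directional wedges by a binary tree of fan filters
upsampled on the quincunx lattice $D = \begin{pmatrix}1 & -1\\ 1 &
1\end{pmatrix}$ ($|\det D| = 2$).

Perfect reconstruction of each two-channel stage is the **Bezout
identity**

$$H_0(z)\,G_0(z) + H_1(z)\,G_1(z) = 1 .$$

Both filter families are constructed so this holds *exactly in tap
arithmetic*, not just approximately:

* **Pyramid ("9-7", "maxflat").** $h_0$ and $g_0$ are separable
  products of the CDF 9/7 (or binomial) lowpass pairs normalized to
  unit DC gain; $h_1 = \delta - h_0 * g_0$ and $g_1 = \delta$ (the
  nonsubsampled Laplacian structure). Then $H_0G_0 + H_1 \cdot 1 = 1$
  identically, and $h_1$ annihilates constants.
* **Fan ("pkva", "dmaxflat").** A zero-phase fan kernel $f$ with
  $F \approx 1$ on one frequency wedge, $\approx 0$ on the complement
  and $F(0,0) = \tfrac12$ is built by a Chebyshev (McClellan-type)
  change of variable $t = (\cos\omega_1 - \cos\omega_2)/2$: for
  "pkva" the odd step polynomial comes from the published pkva12
  ladder half-band coefficients, for "dmaxflat" from the maximally
  flat odd polynomial of degree 7. The quad
  $h_0 = f,\; g_0 = 2\delta - f,\; h_1 = g_1 = \delta - f$
  gives $F(2-F) + (1-F)^2 = 1$ identically.

Because every quad is a polynomial in a *single* convolution operator,
analysis and synthesis commute even when the image is mirror-extended,
so the measured round-trip error is at floating-point level
(~$10^{-15}$) under both boundary modes. Shift invariance is exact
under periodic extension, which is what the invariance tests use;
fusion runs default to symmetric extension to avoid wrap-around
content leaking across the frame.

The directional tree upsamples the fan pair by $D^{d-1}$ at depth $d$.
The original NSCT toolbox switches to parallelogram resampling matrices
from depth 3 on, which yields cleaner wedges at 8 and 16 directions;
the quincunx-power tree used here keeps perfect reconstruction, size
preservation, linearity and shift invariance (all tested) at the cost
of some wedge purity at the finer direction counts. This is a
deliberate simplification: none of the fusion rules depend on wedge
purity, only on the bands forming an invertible, shift-invariant
partition.

Scale ordering: `directions` is given coarsest-to-finest, so the
default `c(4, 8, 8, 16)` puts 16 directions at the finest scale, where
orientation is most informative. Reconstruction is unaffected by this
labeling choice.

## Low-pass fusion: sparse coding over a learned dictionary

The two low-pass bands $L_A, L_B$ are cut into all overlapping
$8\times8$ patches (stride 1). Each patch is vectorized (column-major),
its mean removed and stored. Fusion then runs per position $i$:

1. **Joint sparse coding (SOMP).** Both zero-mean vectors are coded
   over the dictionary $\Phi$ with simultaneous orthogonal matching
   pursuit: the greedy atom choice maximizes the *summed* absolute
   correlation with both residuals, so the two codes share one
   support; each signal's coefficients are its least-squares fit on
   that support. Coding stops when both residual norms fall to
   $\varepsilon$ or `max_atoms` atoms are selected.
2. **Max-L1 selection.** The code with the larger $\ell_1$ norm wins —
   larger sparse-coefficient mass signals more salient structure. Ties
   go to source B (the literal "otherwise" branch), so self-fusion is
   deterministic.
3. **Patch rebuild.** $V_F = \Phi\,\alpha_F + \bar v_F \mathbf 1$,
   where $\bar v_F$ is the *winner's* stored mean.
4. **Overlap-add.** Patches are accumulated at their origins and each
   pixel divided by its coverage count (64 in the interior at stride
   1, down to 1 at the corners).

The dictionary is learned from the image pair being fused:

* patches from *both* low-pass bands are pooled and partitioned into
  `n_clusters = 8` clusters by k-means (k-means++ seeding, Lloyd
  updates, fixed seed). k-means is implemented in-package because the
  contract here — empty clusters dropped with a warning, bit-exact
  determinism given the seed — differs from what `stats::kmeans`
  offers (it errors on empty Lloyd clusters and has no k-means++
  initializer);
* each cluster contributes the smallest number $p$ of leading
  eigenvectors of its second-moment matrix whose eigenvalue mass
  reaches $\delta = 0.95$ — enough atoms to represent the cluster with
  at most 5% residual energy, few enough to stay compact. Patch
  vectors are already zero-mean per patch, so no further per-cluster
  centering is applied. Equal-eigenvalue ties are resolved by a fixed
  sign convention (first nontrivial component positive) so the
  dictionary is byte-reproducible;
* sub-dictionaries are concatenated into $\Phi$ with recorded offsets.

A fully degenerate pair (every cluster all-zero, e.g. two constant
images) would leave no atoms; `learn_dictionary` then returns a
one-atom canonical-basis dictionary, all codes stay zero, and the
output follows the tie rule (source B's mean everywhere).

## High-pass fusion: SML-MAX

Directional coefficients are compared by their local clarity. The
Modified Laplacian

$$\mathrm{ML}(i,j) = |2I_{i,j} - I_{i-s,j} - I_{i+s,j}| +
  |2I_{i,j} - I_{i,j-s} - I_{i,j+s}|, \qquad s = 1$$

is summed, squared, over a $(2P{+}1)\times(2Q{+}1)$ window
($P = Q = 1$, the standard $3\times3$ choice) to give SML. Per pixel
the fused coefficient is copied from the band with the larger SML
(ties to the first source, the non-strict branch). Coefficients are
never blended, so no new intermediate values — and no new ringing —
are introduced. The directional bands produced by the forward
transform are used directly; they are not decomposed a second time,
which would double-filter the detail.

Boundary handling for ML and SML is mirror extension, which keeps
border activity estimates unbiased (periodic wrapping would let
content from the opposite edge inflate them).

## Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `levels` | 4 | pyramid scales |
| `directions` | 4, 8, 8, 16 | wedges per scale, coarse to fine |
| `pyramid_filter` | `"9-7"` | CDF 9/7-derived nonsubsampled pyramid |
| `fan_filter` | `"pkva"` | ladder-coefficient fan pair |
| `patch_size` | 8 px | low-pass patch side |
| `stride` | 1 px | maximal overlap; the overlap-average step presumes it |
| `eps` | $0.01\sqrt{n} = 0.08$ | SOMP stop: 0.01 RMS per pixel on [0,1] data |
| `max_atoms` | 16 | termination guarantee for SOMP |
| `n_clusters` | 8 | joint patch clusters |
| `delta` | 0.95 | retained eigenvalue mass per cluster |
| `sml_step`, `sml_p`, `sml_q` | 1, 1, 1 | ML spacing, $3\times3$ SML window |
| `boundary` | `"symmetric"` | mirror extension for fusion runs |
| `seed` | 0 | clustering initialization |

`stride`, `eps`, `max_atoms`, `n_clusters` and the SML window are not
fixed by the reference setting and are exposed; the values above are
the package's documented choices.

## Synthetic fixtures and what passing tests show

`make_multifocus_pair` renders a band-limited-noise texture plus a
smooth large-scale component, then Gaussian-blurs complementary halves
(or a disk) of it into the two sources, keeping the sharp scene as
ground truth. `make_multimodal_pair` renders one blob phantom under
two disjoint intensity mappings so each structure is visible in
exactly one modality. Both are bit-reproducible from their seed.

These fixtures exercise the mechanics the method relies on —
complementary local sharpness, complementary structure visibility —
with a known target, which real data never provides. They do *not*
emulate modality-specific noise statistics, intensity nonlinearity
between modalities, or registration error; results on them bound the
method's behavior under ideal registration only. Default test
problem sizes are 256×256 for the end-to-end multi-focus study,
128×128 for self-fusion fidelity, and 32–64 px images for unit
properties; all were chosen so each property is measured at the
smallest size where it is meaningful.

## Numerical choices and degenerate inputs

* All arithmetic in double precision; images normalized to [0, 1].
* Convolution runs through the FFT with the kernel wrapped on the
  (padded) grid; kernels larger than the image wrap correctly. Exact
  zeros (e.g. SML of a delta outside its window) are therefore exact
  only to ~$10^{-16}$.
* Max-L1 ties select source B; SML ties select source A — both are the
  literal branch structure of the respective rules, and both matter
  only on measure-zero ties (self-fusion, synthetic constants).
* Metric conventions: MI uses 256 bins and natural summation in bits
  with no normalization; QAB/F uses the published sigmoid constants
  (0.9994, −15, 0.5; 0.9879, −22, 0.8), so a perfect fusion scores
  ≈ 0.975, not 1; flat inputs (edge energy below $10^{-8}$/pixel)
  score 0 by convention. QY uses a 7×7 window, SSIM constants
  $C_1 = 10^{-4}, C_2 = 9\times10^{-4}$, and the 0.75 similarity
  switch between the weighted and max branches.
* Output pixels are clipped — not rescaled — to [0, 1], preserving the
  radiometry of unsaturated pixels.
* Color images: the stated convention is BT.601 luma fusion with
  chroma copied per pixel from the source that won the majority of
  low-pass patch selections; an independent per-channel mode exists.
  (The color behavior is a package convention; the underlying method
  is defined for single-channel images.)

## Known limitations

* Directional wedge purity at 8/16 directions is approximate (quincunx
  powers instead of parallelogram resampling).
* Dictionary learning is per image pair; fusing many pairs of the same
  modality re-learns each time unless a saved dictionary is reused.
* Exactly two sources; no registration; grayscale or RGB only.
* Metrics beyond MI/QAB/F/QY (phase-congruence, perceptual and
  information-theoretic variants) are reserved fields, not computed.
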