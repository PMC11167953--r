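---
title: "Deformable multi-modal registration of histology and specimen snapshots: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable multi-modal registration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The registration problem

Validating optical tissue measurements against histopathology requires
aligning two images of the same tissue slice acquired in very different
ways: a macroscopic camera snapshot of the fresh specimen and a microscopic
H&E section. Histopathological processing (fixation, dehydration,
embedding, cutting, staining) deforms the section nonrigidly — shrinkage,
stretching, compression, tears, holes — so a rigid or affine alignment is
not enough, and the two modalities differ so strongly in colour, contrast
and texture that landmark matching is unreliable.

`ddfreg` addresses this with a VoxelMorph-style formulation: a
convolutional network `g_theta(F, M)` maps a fixed image `F` and a moving
image `M` (stacked as two channels) to a dense displacement field (DDF)
`phi`, a per-pixel 2-vector `(dx, dy)` in pixel units. A differentiable
spatial transformer resamples `M` at `(x + dx, y + dy)` (backward warping
with bilinear interpolation), producing the registered image `M(phi)`.
Training minimises

```
L(F, M, phi) = Lsim(F, M(phi)) + lambda * Lsmooth(phi)
```

with either of two similarity terms:

* **Unsupervised**: `Lsim = -MI(F, M(phi))`, a mutual information computed
  from the joint intensity histogram. MI is the right similarity for
  multi-modal pairs because it rewards statistical dependence rather than
  intensity equality; MSE between a pink histology rendering and a flesh
  coloured snapshot is meaningless even at perfect alignment.
* **Supervised**: `Lsim = MSE(gamma, M(phi))` against a ground-truth label
  image `gamma` — the original (undeformed) snapshot — usable when a
  manually registered reference exists. Here prediction and label share a
  modality, so the plain pixel-wise error is appropriate.

`Lsmooth` is the diffusion regulariser: the mean squared forward-difference
gradient of the two displacement components. The package's scaling
convention is `0.5 * sum_{c in {dx,dy}} [mean((Dx c)^2) + mean((Dy c)^2)]`,
each mean over the valid differences, so a spatially constant field
(a translation) scores exactly 0 and a unit shear (`dx = x`) scores 0.5.

## Differentiable mutual information

The evaluation metric is the hard-binned histogram MI (`histogram_mi()`):
32 equal bins on [0, 1], natural logarithm, zero-probability cells
contribute zero. Hard binning has no useful gradient, so the training loss
(`soft_mi_loss()`) replaces the indicator assignment with Gaussian
(Parzen-window) soft binning: pixel `v` contributes to bin `j` with weight
proportional to `exp(-(v - c_j)^2 / (2 h^2))`, normalised over bins. As the
bandwidth `h` shrinks the soft MI converges to the hard-binned value; the
default `h = 0.02` (roughly two thirds of a bin width at 32 bins) keeps
gradients informative across neighbouring bins without oversmoothing the
joint density. The gradient with respect to the warped image's pixels is
analytic (no stochastic estimator), flows through the bilinear warp to the
field, and from there through the network by ordinary backpropagation.
Bin count is exposed because absolute MI values depend on it; the package
never claims its MI scale matches values computed with other binnings.

## The network

The network is a small encoder-decoder with skip connections operating on
256 wide x 192 high grayscale pairs: stride-2 3x3 convolutions with
LeakyReLU(0.2) and channels (16, 32, 32, 32), a decoder with channels
(32, 32, 32, 32) interleaved with 2x nearest upsampling and skip
concatenation, a 16-channel full-resolution convolution, and a linear
two-channel flow head. The flow head is initialised with standard
deviation 1e-5 and zero bias so that a fresh network predicts essentially
the identity transform (maximum displacement below 0.1 px) — optimisation
starts from "do nothing" rather than from a random warp. The optimiser is
Adam (default learning rate 0.001, standard beta parameters); the
reference schedule is 200 epochs x 100 steps with batch size 16, and the
checkpoint kept is the epoch with the best validation loss. All
convolutions, the transformer and their gradients are implemented directly
(im2col/GEMM with hand-derived backward passes, verified against finite
differences in the test suite); no external deep-learning runtime is used.

## Elastic deformation augmentation

Synthetic deformations emulate what histopathological processing does to a
section. A random field is drawn i.i.d. uniform(-1, 1) per pixel for each
displacement component, convolved with a unit-sum Gaussian kernel of
standard deviation `sigma` (the elasticity coefficient) and side `F`
(reflective boundary), and scaled by `alpha`. The sampling ranges
`sigma in [70, 90]`, `alpha in [11000, 13000]`, `F in [350, 450]` describe
deformations at native camera resolution (around 1000 px wide); since the
network operates at 256 x 192, the package deforms at native resolution
first and resizes afterwards. When a field must be produced directly at
another resolution, `rescale_deformation_ranges()` scales `sigma` and `F`
linearly with the resize factor `f` and `alpha` with `f^2`: the unit-sum
kernel's amplitude scales as `1/f`, so only the extra factor of `f` on
`alpha` keeps displacement proportional to image size. For controlled
recovery experiments, `apply_augmentation(target_max_px = c(lo, hi))`
rescales each field so its maximum displacement magnitude equals a uniform
draw from a stated band — deformation strength is then exact by
construction rather than approximate.

Whether `alpha` multiplies before or after the smoothing is mathematically
irrelevant (convolution is linear); it is applied after. Warping clamps
out-of-bounds samples to the border; smoothing reflects. Fields are
reported for folding (count of negative-Jacobian pixels) but folding is
not prevented — the method does not claim diffeomorphic transforms.

## Preprocessing

* Histology RGB is converted to grayscale with the weighted average
  `0.299 R + 0.587 G + 0.114 B`.
* Snapshots are converted using HSV saturation only,
  `S = (max - min) / max` (0 where `max = 0`). The HSV cone formula is the
  package's documented choice; HSL would differ. Saturation suppresses the
  achromatic background and narrows the intensity gap between modalities.
* Grayscale conversion happens before resizing; resizing to 256 x 192 uses
  coverage-weighted area averaging when downscaling (anti-aliased, exact
  block means at integer factors) and bilinear interpolation when
  upscaling; masks use nearest-neighbour. 8-bit files are divided by 255
  on load; all internal math is double precision.
* Dice requires binary masks and no binarisation rule comes with the data,
  so `foreground_mask()` applies Otsu's threshold, chooses the polarity
  whose class occupies less of the image border (tissue rarely touches the
  frame — this also makes the mask invariant to contrast inversion), keeps
  the largest connected component and fills holes. A constant image yields
  an all-ones mask with a warning.

## The phantom generator

Clinical snapshot-histology datasets with manually registered ground
truth are rare and almost always private, so the package ships a phantom
module that makes every stage testable: two renderings of the same
geometry that differ the way the two modalities do. The foreground is a
thresholded sum of six random Gaussian bumps (smooth, organic, convex-ish
outlines); `n_structures` elliptical internal structures are placed in the
blob interior with a minimum separation so each survives as a connected
component. The histology-like rendering uses a fixed pink/purple palette
with fine-grain noise; the snapshot-like rendering uses a flesh/yellow
palette with coarse multiplicative shading. Palettes are fixed constants
(chosen so both grayscale maps separate background, tissue and structures,
and so the per-channel gap between renderings is large), which keeps
regression tests stable. With probability `artifact_rate` the
histology-like rendering receives a tear (a thin background-coloured
polyline crack walked from the boundary toward the centroid) or a hole
(a background-coloured ellipse); artifacts alter the rendering only, never
the stored geometry masks.

What the phantom does **not** emulate: real stain variability, cellular
texture, illumination and perspective effects of specimen photography,
out-of-plane sectioning, and correlated multi-structure deformation.
Passing phantom tests therefore demonstrates that the machinery (losses,
gradients, warping, training dynamics) behaves correctly and that the
method can recover controlled elastic deformations across a synthetic
modality gap — not that clinical-grade accuracy transfers to real data.

## Desk-scale study sizes

The package's own experiments (test suite and acceptance script) run on
one CPU and use deliberately scaled-down problem sizes, chosen once as the
smallest sizes at which the recovery signal is stable: 30 phantom pairs at
512 x 384 native resolution, one deformed variant each with **mean**
displacement magnitude drawn from 3-8 px at model scale (the mean, not the
peak, is what governs how far mask boundaries move and hence how much
overlap a deformation destroys), a 20/4/6 group-aware split, and 10 epochs
x 20 steps with batch size 2 for the unsupervised model. A schedule 100x
shorter than the reference one needs a proportionally larger step size:
the scaled runs use learning rate 0.003 (unsupervised) and 0.005
(supervised single-pair overfit, 200 steps); the reference learning rate
0.001 is tuned for 20,000 steps and barely moves the network in 200,
while 0.01 destabilises both objectives at these batch sizes. Training
additionally applies global L2 gradient-norm clipping (default ceiling 1,
`clip_norm` in `training_config()`): a large displacement excursion can
push the warp out of the similarity basin and send the loss on a spike,
and clipping caps those steps without affecting well-behaved ones. The
reference schedule (565 images split 360/90/115, 200 x 100 steps, batch
16, learning rate 0.001) remains the package default in
`training_config()` / `split_spec()`.

## Numerical choices and degenerate inputs

* Natural logarithm throughout MI (affects only the reported scale).
* `lambda = 0.01` by default: small enough not to fight the similarity
  term at 3-8 px deformations, large enough to suppress speckle in the
  field; exposed prominently because no principled universal value exists.
* Joint probabilities are clamped at 1e-300 inside logs; exact zeros
  contribute zero by construction.
* Dice of two empty masks is defined as 1 (vacuous perfect agreement).
* Mann-Whitney U uses the exact null distribution for tie-free samples
  up to n = 20 per group, otherwise a normal approximation with tie and
  continuity corrections; identical constant samples give p = 1.
* A value of exactly 1.0 falls into the top histogram bin; bin edges are
  half-open elsewhere.
* Warping at clamped border samples has zero gradient with respect to the
  field (the sample no longer moves), which is the correct subgradient.
* One root seed spawns named substreams for every random component
  (geometry, textures, artifacts, field draws, initialisation, batch
  sampling), so adding variants or stages never perturbs earlier draws and
  every artefact is reproducible from `(config, seed)`.

## Known limitations

* MI is computed globally; locally varying contrast (as produced by
  staining inhomogeneity) can saturate it even at good alignment, which is
  why Dice on foreground masks accompanies it.
* The smoothness regulariser penalises all gradients, including the true
  deformation's; very strong regularisation biases toward under-warping.
* No diffeomorphic guarantee; strong fields can fold (reported, not
  prevented).
* Normalised MI, patch-wise MI and target registration error are out of
  scope.
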