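# ddfreg: deformable multi-modal registration of histology and specimen snapshot images

`ddfreg` registers two-dimensional multi-modal image pairs — a macroscopic
tissue-specimen snapshot and the corresponding H&E histology section — by
predicting a **dense displacement field** (DDF) with a convolutional
encoder–decoder and warping the moving image through a differentiable
spatial transformer. It is aimed at researchers validating optical tissue
measurements (DRS, hyperspectral, fluorescence imaging) against
histopathology, where tissue processing deforms sections nonrigidly and
manual landmark registration is slow and subjective.

## The model

A network `g_θ(F, M)` maps the fixed image `F` and the moving image `M`
(two stacked grayscale channels, 256 × 192) to a field `φ = (Δx, Δy)`;
`M(φ)` denotes `M` resampled at `(x + Δx, y + Δy)` with bilinear
interpolation. Training minimises

    L(F, M, φ) = Lsim(F, M(φ)) + λ · Lsmooth(φ)

* **Unsupervised** (multi-modal): `Lsim = −HMI(F, M(φ))`, the
  histogram-based mutual information
  `HMI(F, M) = Σ_{i,j} p(i,j) ln [ p(i,j) / (p(i) p(j)) ]`,
  made differentiable by Gaussian (Parzen) soft binning.
* **Supervised**: `Lsim = MSE(γ, M(φ)) = (1/n) Σ_i (γ_i − M(φ)_i)²`
  against a ground-truth label image `γ`.
* `Lsmooth` is the diffusion regulariser (mean squared spatial gradient of
  the field).

Evaluation uses the Dice overlap of foreground masks,
`Dice(A, B) = 2|A∩B| / (|A|+|B|)`, and `HMI`, before and after
registration, with two-sided Mann–Whitney U tests between methods.

The package also provides the elastic-deformation augmentation used for
training data (uniform(−1, 1) noise fields smoothed by a Gaussian of
standard deviation σ ∈ [70, 90] and size F ∈ [350, 450], scaled by
α ∈ [11000, 13000] at native resolution), modality-specific grayscale
conversion (0.299 R + 0.587 G + 0.114 B for histology, HSV saturation for
snapshots), and a synthetic **phantom generator** producing paired
multi-modal images with shared geometry — so the entire pipeline runs and
is tested without any clinical data. Everything numerical (convolutions,
backpropagation, the spatial transformer and the soft-MI gradient) is
implemented in the package itself (R + Rcpp/BLAS); no deep-learning
runtime is required.

## Worked example

Generate paired phantoms, deform the histology rendering, train the
unsupervised model briefly, and register a held-out pair:

```r
library(ddfreg)

pairs <- generate_phantom_dataset(12, phantom_config(seed = 1))
items <- build_registration_dataset(pairs, mode = "unsupervised",
                                    seed = 1, target_px = c(3, 8))
sp  <- split_dataset(items, split_spec(8, 2, 2, seed = 1))
cfg <- training_config("unsupervised", epochs = 5, steps_per_epoch = 20,
                       batch_size = 2, learning_rate = 0.003, seed = 1)
model <- train_registration(sp$train, cfg, val = sp$val)
summary(model)
#> unsupervised registration model, 5 epochs (best: 4)
#>   train loss -0.36869 -> -0.38535
#>   best validation loss -0.40619
res <- register_pair(model, sp$test[[1]]$moving, sp$test[[1]]$fixed)
print(res)
#> Registration result 192 x 256 px
#>   displacement: mean 1.70, max 6.69 px; folded pixels: 42
#>   MI before 0.4330 -> after 0.4548 nats
```

The summary shows the composite loss (negated soft MI plus the smoothness
term) falling as the network learns; the registration result reports the
predicted field's magnitude, a folding diagnostic (42 of 49,152 pixels
have a negative Jacobian — reported, not prevented), and the
mutual-information gain of the warped pair — MI rises by ~0.02 nats after
this deliberately short 5-epoch demonstration, i.e. the warped snapshot
already shares more structure with the deformed histology than the
unwarped one. `evaluate_test_set()` produces the same
before/after bookkeeping (plus Dice on foreground masks) for a whole test
set, and `compare_methods()` runs the Mann–Whitney comparison between two
methods' after-registration metrics.

`run_pipeline(config, out_dir)` chains every stage (phantom generation →
augmentation → preprocessing → group-aware splitting → training →
evaluation → statistical report) and writes metrics CSV, comparison JSON,
training histories and a run log; `inst/scripts/ddfreg` exposes the same
stages as a small CLI.

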