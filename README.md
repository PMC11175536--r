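# ora: object reconstruction-guided attention for robust recognition

Feed-forward classifiers degrade sharply when images are corrupted by
noise, fog, or occlusion. Human vision does not — plausibly because
recognition is supported by top-down feedback that tests object hypotheses
against the evidence. This package implements a computational model of that
idea for researchers in visual attention and object-recognition modelling:
a slot-based encoder–decoder network that *reconstructs* its current best
object hypothesis and uses the reconstruction as top-down attention, plus
the synthetic data and corruption machinery needed to study it on a desk,
with no downloads.

## The model

An encoder maps a grayscale image to **feature slots** (8-dim capsule-like
vectors, squashed so that `||v||` ∈ [0, 1)); a learned vote tensor maps
them to **object slots** (one 16-dim vector per class) whose norm is the
class likelihood; a dense decoder reconstructs the image from one object
slot. Training minimises margin loss plus `λ_recon = 0.392` times the
reconstruction MSE. At inference, two attention mechanisms run:

- **Feature binding** (3 iterations per forward step): vote weights are
  modulated by `c_ij = b_ij · r_ij ∈ [0.25, 1]`, the product of a
  vote–object similarity score and a per-class reconstruction score
  (negative MSE), each MaxMin-normalized over classes and floored at 0.5.
  The class likelihood is then adjusted by the reconstruction score.
- **Spatial masking** (up to 5 forward steps): while the entropy of the
  class-likelihood distribution stays above 0.6 nats, the best hypothesis's
  reconstruction is thresholded at 0.1 into a boolean mask that suppresses
  input pixels outside the hypothesized shape, and the masked, renormalized
  input feeds the next step. The number of steps taken is the model's
  **reaction time**.

A matched CNN baseline (same encoder, two dropout-regularized readout
layers, NLL loss) is included, as are a ten-class synthetic glyph
generator, a seeded corruption suite (gaussian/impulse noise, fog, stripe,
zigzag, dotted line, spatter, blur, affine), readers for MNIST IDX and
MNIST-C-style `.npy` containers, and a sequential extension that
recognizes overlapping objects one at a time by explaining away each found
object's pixels.

## Worked example

```r
library(ora)

glyphs <- generate_glyphs(glyph_spec(samples_per_class = 500, seed = 1))
split  <- glyph_split(glyphs, test_fraction = 0.1, seed = 2)

fit <- ora(split$train$images, split$train$labels,
           train = train_config(profile = "glyph-test", max_epochs = 3, seed = 0))
print(fit)
#> Reconstruction-guided attention model (small_cnn encoder), 10 classes, 28x28 input
#>   1152 feature slots (dim 8), 10 object slots (dim 16)
#>   2,904,720 trainable parameters
#>   trained 3 epoch(s); best validation accuracy 0.998 (epoch 2)

# one fog-corrupted image, watched through the attention loop
img <- corrupt(split$test$images[4, , ], corruption_spec("fog", 4, seed = 7))
tr  <- recognize(img, fit)
tr$rt_steps          # forward steps used (the model's reaction time)
#> [1] 5
tr$final_prediction - 1
#> [1] 0
round(tr$entropies, 3)
#> [1] 1.118 0.802 0.812 0.812 0.812

# ablation suite on a corrupted evaluation set
ab <- ablation_suite(fit, split$test$images[1:40, , ], split$test$labels[1:40],
                     list(corruption_spec("gaussian_noise", 4, seed = 0),
                          corruption_spec("fog", 4, seed = 0)))
print(ab)
#> Ablation suite (+/- spatial masking, +/- feature binding)
#>   condition accuracy mean_rt
#>        full   0.6750  3.1125
#>  no_spatial   0.4625  1.0000
#>  no_binding   0.4250  5.0000
#>        none   0.5375  1.0000
```

Read: heavy fog never lets this trial's entropy cross the 0.6-nat
threshold, so the model spends all 5 forward steps — a "long" reaction
time — and still lands on the correct class (0). On the 80-image
severity-4 evaluation set the full model scores 67.5%; removing spatial
masking costs ~21 points (the mask is what filters fog and noise out of
the input), and removing feature binding drives every trial to the 5-step
reaction-time cap because the raw slot norms alone keep the entropy above
threshold. Clean glyphs are recognized in ~1.1 steps on average.

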