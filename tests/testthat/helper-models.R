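# Shared fixtures, built in code. The expensive trained model is memoised in
# a package-local environment so it is trained once per test run and reused
# by every file that needs real weights.

.fixtures <- new.env(parent = emptyenv())

# A tiny hand-configurable slot model: no encoder (features supplied
# directly), 3 feature slots of dim 2, 2 object slots of dim 2, a 3x3-pixel
# decoder. Weights are drawn from the given seed and can be overwritten.
toy_model <- function(nf = 3, df = 2, no = 2, do_ = 2, img = 3, seed = 1) {
  cfg <- ora_config(encoder = "none", image_size = img, n_classes = no,
                    d_feature = df, d_object = do_,
                    decoder_hidden = c(5, 6), n_feature_slots = nf,
                    seed = seed)
  m <- ora_model(cfg)
  m$kind <- "ora"
  m$trained <- TRUE
  m
}

# The full-scale dataset and fitted model used by the integration and
# acceptance tests: 5,000 glyphs (500 per class), 10% held out, the
# two-conv 28x28 preset trained for 3 epochs with the glyph-scale profile.
shared_glyphs <- function() {
  if (is.null(.fixtures$glyphs)) {
    g <- generate_glyphs(glyph_spec(samples_per_class = 500, seed = 1))
    .fixtures$glyphs <- glyph_split(g, test_fraction = 0.1, seed = 2)
  }
  .fixtures$glyphs
}

shared_fit <- function() {
  if (is.null(.fixtures$fit)) {
    sp <- shared_glyphs()
    .fixtures$fit <- ora(sp$train$images, sp$train$labels,
                         train = train_config(profile = "glyph-test",
                                              max_epochs = 3, seed = 0))
  }
  .fixtures$fit
}

# Stub model for loop-contract tests: recognize() consults $step_fn.
# `script` is a list with one element per step: list(scores =, recon =).
stub_model <- function(script, n_classes = 10, image_size = 8) {
  list(config = list(n_classes = n_classes, image_size = image_size),
       step_fn = function(image, step) {
         s <- script[[min(step, length(script))]]
         list(scores = s$scores, reconstruction = s$recon)
       })
}

uniform_scores <- function(n = 10) rep(1, n)
onehot_scores <- function(j, n = 10) { s <- rep(0, n); s[j] <- 1; s }
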