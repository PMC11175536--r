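# Model architecture: a CNN backbone whose flattened feature map is regrouped
# into low-level "feature slots" (8-dim capsule-like vectors), a bias-free
# vote tensor mapping every feature slot to every object slot, and a dense
# decoder that reconstructs the input image from a single object slot.

#' Model configuration
#'
#' Builds the architecture description for an object-slot model. The feature
#' slot count is derived from the encoder geometry and image size: the
#' two-conv backbone (two 3x3 valid convolutions with 32 and 64 channels and
#' one 2x2 max-pool) maps a 28x28 input to a 12x12x64 map, i.e. 1152 feature
#' slots of dimension 8. The compact residual encoder pools to 6x6x64 = 288
#' slots. Object slots are one per class, 16-dim by default, and their vector
#' norm is the class likelihood.
#'
#' @param encoder `"small_cnn"`, `"resnet18_small"`, or `"none"` (slots are
#'   supplied directly; used for hand-built toy models).
#' @param image_size Input side length in pixels.
#' @param n_classes Number of object slots.
#' @param d_feature,d_object Feature / object slot dimensions.
#' @param decoder_hidden Widths of the two hidden decoder layers.
#' @param n_feature_slots Required when `encoder = "none"`.
#' @param seed Integer seed used when initialising parameters.
#' @return A list of class `ora_config`.
#' @export
ora_config <- function(encoder = c("small_cnn", "resnet18_small", "none"),
                       image_size = 28, n_classes = 10, d_feature = 8,
                       d_object = 16, decoder_hidden = c(512, 1024),
                       n_feature_slots = NULL, seed = 0) {
  encoder <- match.arg(encoder)
  if (encoder == "small_cnn") {
    if ((image_size - 4) %% 2 != 0)
      stop("small_cnn encoder needs (image_size - 4) divisible by 2")
    side <- (image_size - 4) / 2
    flat <- side^2 * 64
  } else if (encoder == "resnet18_small") {
    s1 <- image_size %/% 2          # stem + pool
    s2 <- s1 - 2                    # valid 3x3 projection conv
    if (s2 <= 0 || s2 %% 2 != 0)
      stop("resnet18_small encoder needs (image_size %/% 2 - 2) even and positive")
    side <- s2 / 2
    flat <- side^2 * 64
  } else {
    if (is.null(n_feature_slots))
      stop("encoder = 'none' requires n_feature_slots")
    flat <- n_feature_slots * d_feature
    side <- NA_integer_
  }
  if (flat %% d_feature != 0) stop("backbone output not divisible by d_feature")
  structure(list(
    encoder = encoder, image_size = as.integer(image_size),
    n_classes = as.integer(n_classes), d_feature = as.integer(d_feature),
    d_object = as.integer(d_object),
    n_feature_slots = as.integer(flat / d_feature),
    feat_side = as.integer(side),
    decoder_hidden = as.integer(decoder_hidden), seed = as.integer(seed)
  ), class = "ora_config")
}

#' Construct an (untrained) object-slot model
#'
#' Allocates and seeds all trainable parameters for the configuration:
#' backbone convolutions, the bias-free feature-to-object vote tensor
#' (`n_feature_slots * d_feature` by `n_classes * d_object`), and the
#' three-layer dense decoder ending in a sigmoid. With the default 28x28
#' two-conv preset the trainable parameter total is 2,904,720.
#'
#' @param config An [ora_config()].
#' @return A list of class `ora_model` with elements `config` and `params`.
#' @export
ora_model <- function(config = ora_config()) {
  stopifnot(inherits(config, "ora_config"))
  with_seed(config$seed, {
    p <- list()
    if (config$encoder == "small_cnn") {
      p$conv1_w <- init_conv(3, 3, 1, 32); p$conv1_b <- numeric(32)
      p$conv2_w <- init_conv(3, 3, 32, 64); p$conv2_b <- numeric(64)
    } else if (config$encoder == "resnet18_small") {
      p$stem_w <- init_conv(3, 3, 1, 32); p$stem_b <- numeric(32)
      p$res1a_w <- init_conv(3, 3, 32, 32); p$res1a_b <- numeric(32)
      p$res1b_w <- init_conv(3, 3, 32, 32); p$res1b_b <- numeric(32)
      p$proj_w <- init_conv(3, 3, 32, 64); p$proj_b <- numeric(64)
    }
    din <- config$n_feature_slots * config$d_feature
    dout <- config$n_classes * config$d_object
    p$vote_w <- init_dense(din, dout, sd = sqrt(1 / din))
    h <- config$decoder_hidden
    pix <- config$image_size^2
    p$dec1_w <- init_dense(dout, h[1]); p$dec1_b <- numeric(h[1])
    p$dec2_w <- init_dense(h[1], h[2]); p$dec2_b <- numeric(h[2])
    p$dec3_w <- init_dense(h[2], pix, sd = sqrt(1 / h[2])); p$dec3_b <- numeric(pix)
    structure(list(config = config, params = p, trained = FALSE),
              class = "ora_model")
  })
}

#' Loss configuration
#'
#' @param lambda_recon Weight of the reconstruction MSE in the total loss
#'   (default 0.392).
#' @param margin Margin `m` of the hinge-squared classification loss; the
#'   target slot norm is pushed above `1 - m`, non-targets below `m`.
#' @param target_sf_band Spatial-frequency band of the reconstruction target:
#'   `"full"`, `"low"`, or `"high"`.
#' @param sf_cutoffs Low/high cutoff frequencies in cycles per image.
#' @return A list of class `ora_loss_config`.
#' @export
loss_config <- function(lambda_recon = 0.392, margin = 0.1,
                        target_sf_band = c("full", "low", "high"),
                        sf_cutoffs = c(low = 6, high = 30)) {
  stopifnot(lambda_recon >= 0, margin > 0, margin < 0.5)
  structure(list(lambda_recon = lambda_recon, margin = margin,
                 target_sf_band = match.arg(target_sf_band),
                 sf_cutoffs = sf_cutoffs),
            class = "ora_loss_config")
}

# ---- slot/feature-map reshapes --------------------------------------------

# (N,H,W,C) feature map -> ((N*Nf) x d) matrix of slot vectors; slots are
# (position, channel-group) pairs, the d channels within a group forming the
# slot vector.
featmap_to_slotrows <- function(fm, d) {
  dd <- dim(fm); n <- dd[1]; hw <- dd[2] * dd[3]; g <- dd[4] / d
  dim(fm) <- c(n, hw, d, g)
  fm <- aperm(fm, c(1, 2, 4, 3))
  dim(fm) <- c(n * hw * g, d)
  fm
}

slotrows_to_featmap <- function(rows, n, h, w, cc) {
  d <- ncol(rows); g <- cc / d
  dim(rows) <- c(n, h * w, g, d)
  rows <- aperm(rows, c(1, 2, 4, 3))
  dim(rows) <- c(n, h, w, cc)
  rows
}

# ((N*G) x d) slot rows (sample index fastest) <-> (N, G*d) flat matrix with
# the d components contiguous per slot.
ungroup_rows <- function(rows, n, d) {
  g <- nrow(rows) / n
  dim(rows) <- c(n, g, d)
  rows <- aperm(rows, c(1, 3, 2))
  dim(rows) <- c(n, g * d)
  rows
}

group_rows <- function(x, d) {
  n <- nrow(x); g <- ncol(x) / d
  dim(x) <- c(n, d, g)
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(n * g, d)
  x
}

# ---- encoder ---------------------------------------------------------------

# x: (N, S, S, 1). Returns pre-squash slot rows ((N*Nf) x d_f) plus caches.
encoder_forward <- function(model, x, keep_cache = TRUE) {
  p <- model$params; cfg <- model$config
  if (cfg$encoder == "small_cnn") {
    c1 <- conv2d_forward(x, p$conv1_w, p$conv1_b)
    r1 <- relu_forward(c1$out)
    c2 <- conv2d_forward(r1$out, p$conv2_w, p$conv2_b)
    r2 <- relu_forward(c2$out)
    mp <- maxpool2_forward(r2$out)
    cache <- if (keep_cache) list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, mp = mp)
  } else if (cfg$encoder == "resnet18_small") {
    st <- conv2d_forward(x, p$stem_w, p$stem_b, pad = 1)
    rs <- relu_forward(st$out)
    p1 <- maxpool2_forward(rs$out)
    a <- conv2d_forward(p1$out, p$res1a_w, p$res1a_b, pad = 1)
    ra <- relu_forward(a$out)
    b <- conv2d_forward(ra$out, p$res1b_w, p$res1b_b, pad = 1)
    rb <- relu_forward(b$out + p1$out)          # identity skip
    pj <- conv2d_forward(rb$out, p$proj_w, p$proj_b)
    rj <- relu_forward(pj$out)
    mp <- maxpool2_forward(rj$out)
    cache <- if (keep_cache) list(st = st, rs = rs, p1 = p1, a = a, ra = ra,
                                  b = b, rb = rb, pj = pj, rj = rj, mp = mp)
  } else stop("encoder 'none' cannot encode images; supply features directly")
  fmap <- mp$out
  slotrows <- featmap_to_slotrows(fmap, cfg$d_feature)
  list(slotrows = slotrows, fmap_dim = dim(fmap), cache = cache)
}

encoder_backward <- function(model, cache, dfmap) {
  p <- model$params; cfg <- model$config
  g <- list()
  if (cfg$encoder == "small_cnn") {
    dmp <- maxpool2_backward(cache$mp, dfmap)
    dr2 <- relu_backward(cache$r2, dmp)
    b2 <- conv2d_backward(cache$c2, p$conv2_w, dr2)
    g$conv2_w <- b2$dw; g$conv2_b <- b2$db
    dr1 <- relu_backward(cache$r1, b2$dx)
    b1 <- conv2d_backward(cache$c1, p$conv1_w, dr1)
    g$conv1_w <- b1$dw; g$conv1_b <- b1$db
  } else {
    dmp <- maxpool2_backward(cache$mp, dfmap)
    drj <- relu_backward(cache$rj, dmp)
    bpj <- conv2d_backward(cache$pj, p$proj_w, drj)
    g$proj_w <- bpj$dw; g$proj_b <- bpj$db
    drb <- relu_backward(cache$rb, bpj$dx)
    bb <- conv2d_backward(cache$b, p$res1b_w, drb)
    g$res1b_w <- bb$dw; g$res1b_b <- bb$db
    dra <- relu_backward(cache$ra, bb$dx)
    ba <- conv2d_backward(cache$a, p$res1a_w, dra)
    g$res1a_w <- ba$dw; g$res1a_b <- ba$db
    dp1 <- ba$dx + drb                           # skip-connection gradient
    drs <- relu_backward(cache$rs, maxpool2_backward(cache$p1, dp1))
    bs <- conv2d_backward(cache$st, p$stem_w, drs)
    g$stem_w <- bs$dw; g$stem_b <- bs$db
  }
  g
}

# ---- decoder ---------------------------------------------------------------

# odec: (N, n_classes * d_object) with non-selected slots zeroed.
decoder_forward <- function(params, odec, keep_cache = TRUE) {
  d1 <- dense_forward(odec, params$dec1_w, params$dec1_b)
  h1 <- relu_forward(d1$out)
  d2 <- dense_forward(h1$out, params$dec2_w, params$dec2_b)
  h2 <- relu_forward(d2$out)
  d3 <- dense_forward(h2$out, params$dec3_w, params$dec3_b)
  out <- sigmoid(d3$out)
  list(out = out,
       cache = if (keep_cache) list(d1 = d1, h1 = h1, d2 = d2, h2 = h2,
                                    d3 = d3, out = out))
}

decoder_backward <- function(params, cache, dout) {
  dz3 <- dout * cache$out * (1 - cache$out)
  b3 <- dense_backward(cache$d3, params$dec3_w, dz3)
  dh2 <- relu_backward(cache$h2, b3$dx)
  b2 <- dense_backward(cache$d2, params$dec2_w, dh2)
  dh1 <- relu_backward(cache$h1, b2$dx)
  b1 <- dense_backward(cache$d1, params$dec1_w, dh1)
  list(dodec = b1$dx,
       grads = list(dec3_w = b3$dw, dec3_b = b3$db,
                    dec2_w = b2$dw, dec2_b = b2$db,
                    dec1_w = b1$dw, dec1_b = b1$db))
}

# ---- exported architecture operations --------------------------------------

#' Encode an image into squashed feature slots
#'
#' Runs the backbone and regroups the flattened feature map into
#' `n_feature_slots` vectors of dimension `d_feature`, each squashed so its
#' norm lies in `[0, 1)`.
#'
#' @param image An `image_size` x `image_size` matrix in `[0, 1]`, or an
#'   (N, S, S) array for a batch.
#' @param model An [ora_model()].
#' @return For a single image, an `n_feature_slots` x `d_feature` matrix;
#'   for a batch, an (N, n_feature_slots, d_feature) array.
#' @export
encode_feature_slots <- function(image, model) {
  cfg <- model$config
  single <- is.matrix(image)
  x <- as_image_batch(image, cfg$image_size)
  enc <- encoder_forward(model, x, keep_cache = FALSE)
  fsq <- squash_rows(enc$slotrows)
  n <- dim(x)[1]
  dim(fsq) <- c(n, cfg$n_feature_slots, cfg$d_feature)
  if (single) fsq[1, , ] else fsq
}

as_image_batch <- function(image, image_size) {
  if (is.matrix(image)) {
    if (!all(dim(image) == image_size))
      stop(sprintf("image is %dx%d but the model expects %dx%d",
                   nrow(image), ncol(image), image_size, image_size))
    array(image, c(1, image_size, image_size, 1))
  } else if (length(dim(image)) == 3) {
    if (!all(dim(image)[2:3] == image_size))
      stop(sprintf("images are %dx%d but the model expects %dx%d",
                   dim(image)[2], dim(image)[3], image_size, image_size))
    array(image, c(dim(image), 1))
  } else stop("image must be a matrix or an (N, S, S) array")
}

#' Compute feature-to-object votes
#'
#' Each feature slot casts a vote for each object slot through its learned
#' linear map: `votes[i, j, ] = W_ij f_i`.
#'
#' @param features `n_feature_slots` x `d_feature` matrix of (squashed)
#'   feature slots.
#' @param model An [ora_model()] supplying the vote tensor.
#' @return An `n_feature_slots` x `n_classes` x `d_object` array.
#' @export
compute_votes <- function(features, model) {
  cfg <- model$config
  if (!is.matrix(features) || nrow(features) != cfg$n_feature_slots ||
      ncol(features) != cfg$d_feature)
    stop(sprintf("features must be %d x %d, got %d x %d",
                 cfg$n_feature_slots, cfg$d_feature,
                 nrow(features), ncol(features)))
  v <- votes_matrix(features, model)
  dim(v) <- c(cfg$n_feature_slots, cfg$d_object, cfg$n_classes)
  aperm(v, c(1, 3, 2))
}

# Votes as an (Nf x n_classes*d_object) matrix, row i = concatenated votes of
# feature slot i. Uses 8 elementwise products against cached row-slices of
# the vote tensor instead of Nf tiny matmuls.
votes_matrix <- function(features, model) {
  cfg <- model$config
  sl <- vote_slices(model)
  v <- 0
  for (k in seq_len(cfg$d_feature)) v <- v + features[, k] * sl[[k]]
  v
}

vote_slices <- function(model) {
  cfg <- model$config
  lapply(seq_len(cfg$d_feature), function(k)
    model$params$vote_w[seq(k, by = cfg$d_feature,
                            length.out = cfg$n_feature_slots), , drop = FALSE])
}

#' Decode an object slot into an image reconstruction
#'
#' The decoder consumes the full object-slot tensor with every slot except
#' `j` zeroed, so one decoder serves both most-activated-slot decoding and
#' per-class decoding during feature binding.
#'
#' @param objects `n_classes` x `d_object` matrix of (squashed) object slots.
#' @param j Class index (1-based) of the slot to decode.
#' @param model An [ora_model()].
#' @return An `image_size` x `image_size` reconstruction with intensities in
#'   `[0, 1]`.
#' @export
decode_reconstruction <- function(objects, j, model) {
  cfg <- model$config
  if (length(j) != 1 || j < 1 || j > cfg$n_classes)
    stop("j must be a single class index in 1..n_classes")
  odec <- matrix(0, 1, cfg$n_classes * cfg$d_object)
  cols <- ((j - 1) * cfg$d_object + 1):(j * cfg$d_object)
  odec[1, cols] <- objects[j, ]
  out <- decoder_forward(model$params, odec, keep_cache = FALSE)$out
  matrix(out, cfg$image_size, cfg$image_size)
}

# Decode all classes at once from a flat (n_classes*d_object) slot vector;
# returns an (n_classes x pixels) matrix. Inference hot path.
decode_all_classes <- function(params, oflat, n_classes, d_object) {
  odec <- matrix(0, n_classes, n_classes * d_object)
  for (j in seq_len(n_classes)) {
    cols <- ((j - 1) * d_object + 1):(j * d_object)
    odec[j, cols] <- oflat[cols]
  }
  decoder_forward(params, odec, keep_cache = FALSE)$out
}

# ---- losses ----------------------------------------------------------------

#' Margin classification loss
#'
#' Hinge-squared loss on object-slot norms: the target slot's norm is pushed
#' above `1 - m` and every non-target norm below `m`. Zero iff the target
#' norm is at least `1 - m` and all non-target norms are at most `m`.
#'
#' @param slot_norms Numeric vector of object-slot vector norms in `[0, 1)`.
#' @param target One-hot vector of the same length (or a single 1-based
#'   class index).
#' @param m Margin, default 0.1.
#' @return Nonnegative scalar.
#' @examples
#' margin_loss(c(0.5, 0), c(1, 0))   # (0.9 - 0.5)^2 = 0.16
#' margin_loss(c(0.95, 0.3), c(1, 0)) # (0.3 - 0.1)^2 = 0.04
#' @export
margin_loss <- function(slot_norms, target, m = 0.1) {
  if (length(target) == 1)
    target <- as.numeric(seq_along(slot_norms) == target)
  pos <- target * pmax(0, (1 - m) - slot_norms)^2
  neg <- (1 - target) * pmax(0, slot_norms - m)^2
  sum(pos + neg)
}

# Gradient of margin_loss w.r.t. the norms (vectorised over a batch matrix).
margin_loss_grad_norms <- function(norms, target_onehot, m = 0.1) {
  -2 * target_onehot * pmax(0, (1 - m) - norms) +
    2 * (1 - target_onehot) * pmax(0, norms - m)
}

#' Total training loss
#'
#' Classification loss plus `lambda_recon` times the mean squared pixel
#' difference between the reconstruction and its target image. When the loss
#' configuration requests a band-limited reconstruction target, the image is
#' spatial-frequency filtered before the MSE is taken.
#'
#' @param class_loss Scalar classification (margin) loss.
#' @param image Target image matrix in `[0, 1]`.
#' @param reconstruction Reconstruction matrix, same shape.
#' @param cfg An [loss_config()].
#' @return Scalar total loss.
#' @export
total_loss <- function(class_loss, image, reconstruction, cfg = loss_config()) {
  if (!all(dim(image) == dim(reconstruction)))
    stop("image and reconstruction must have identical shape")
  target <- recon_target(image, cfg)
  class_loss + cfg$lambda_recon * mean((target - reconstruction)^2)
}

recon_target <- function(image, cfg) {
  if (cfg$target_sf_band == "full") return(image)
  cutoff <- if (cfg$target_sf_band == "low") cfg$sf_cutoffs[["low"]]
            else cfg$sf_cutoffs[["high"]]
  filter_spatial_frequency(image, cfg$target_sf_band, cutoff)
}

#' Spatial-frequency filtering of an image
#'
#' Applies a Gaussian transfer function in the Fourier domain: the low-pass
#' keeps frequencies below `cutoff` cycles/image
#' (gain `exp(-rho^2 / (2 cutoff^2))`), the high-pass is its complement and
#' removes the DC component entirely. The filtered image is rescaled to
#' `[0, 1]` by MaxMin normalization unless `rescale = FALSE`.
#'
#' @param image Square image matrix.
#' @param band `"low"` or `"high"`.
#' @param cutoff Cutoff frequency in cycles per image, > 0.
#' @param rescale Rescale the output into `[0, 1]`?
#' @return Filtered image matrix.
#' @export
filter_spatial_frequency <- function(image, band = c("low", "high"), cutoff,
                                     rescale = TRUE) {
  band <- match.arg(band)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  n <- nrow(image)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))   # cycles per image
  rho2 <- outer(k^2, k^2, "+")
  gain <- exp(-rho2 / (2 * cutoff^2))
  if (band == "high") gain <- 1 - gain
  out <- Re(stats::fft(stats::fft(image) * gain, inverse = TRUE)) / n^2
  if (rescale) maxmin_normalize(out, 0, 1) else out
}

#' Count trainable parameters
#'
#' @param model An [ora_model()] or fitted `ora_fit`.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "ora_fit")) model <- model$model
  sum(vapply(model$params, length, integer(1)))
}
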