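test_that("encoder presets reproduce the published slot geometry", {
  m <- ora_model(ora_config())
  expect_equal(m$config$n_feature_slots, 1152L)
  expect_equal(m$config$d_feature, 8L)
  f <- encode_feature_slots(matrix(0.5, 28, 28), m)
  expect_equal(dim(f), c(1152, 8))

  mr <- ora_model(ora_config(encoder = "resnet18_small"))
  expect_equal(mr$config$n_feature_slots, 288L)
  fr <- encode_feature_slots(matrix(0.5, 28, 28), mr)
  expect_equal(dim(fr), c(288, 8))

  # all-zero image: the bias response, squashed, with every norm < 1
  f0 <- encode_feature_slots(matrix(0, 28, 28), m)
  expect_true(all(sqrt(rowSums(f0^2)) < 1))

  expect_error(encode_feature_slots(matrix(0, 20, 20), m), "28x28")
})

test_that("batch and single-image encoding agree", {
  m <- ora_model(ora_config(image_size = 12, n_classes = 3, d_object = 4,
                            decoder_hidden = c(8, 9), seed = 3))
  set.seed(1)
  x <- array(runif(2 * 12 * 12), c(2, 12, 12))
  fb <- encode_feature_slots(x, m)
  expect_equal(dim(fb), c(2, m$config$n_feature_slots, 8))
  expect_equal(fb[2, , ], encode_feature_slots(x[2, , ], m), tolerance = 1e-12)
})

test_that("votes are the per-pair linear maps of feature slots", {
  m <- toy_model(nf = 3, df = 2, no = 2, do_ = 2)
  # identity vote maps: votes[i, j, ] must equal f_i
  w <- matrix(0, 6, 4)
  for (i in 1:3) for (j in 1:2)
    w[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- diag(2)
  m$params$vote_w <- w
  f <- matrix(rnorm(6), 3, 2)
  v <- compute_votes(f, m)
  expect_equal(dim(v), c(3, 2, 2))
  for (i in 1:3) for (j in 1:2) expect_equal(v[i, j, ], f[i, ])

  # linearity under a random vote tensor
  m$params$vote_w <- matrix(rnorm(24), 6, 4)
  expect_equal(compute_votes(f * 0, m), array(0, c(3, 2, 2)))
  expect_equal(compute_votes(2 * f, m), 2 * compute_votes(f, m),
               tolerance = 1e-12)
  # hand-checked entry: votes[i,j,] = W_ij f_i
  wij <- m$params$vote_w[3:4, 3:4]       # i = 2, j = 2 block
  expect_equal(compute_votes(f, m)[2, 2, ], as.vector(f[2, ] %*% wij))

  expect_error(compute_votes(matrix(0, 4, 2), m), "must be 3 x 2")
})

test_that("decoder produces deterministic [0,1] images of the configured size", {
  m <- toy_model(img = 4, seed = 9)
  obj <- matrix(rnorm(4), 2, 2)
  r1 <- decode_reconstruction(obj, 1, m)
  expect_equal(dim(r1), c(4, 4))
  expect_true(all(r1 >= 0 & r1 <= 1))
  expect_identical(r1, decode_reconstruction(obj, 1, m))   # bit-identical
  expect_false(isTRUE(all.equal(r1, decode_reconstruction(obj, 2, m))))
  expect_error(decode_reconstruction(obj, 3, m), "class index")
  expect_error(decode_reconstruction(obj, 0, m), "class index")

  # zero weights: a constant bias image
  m$params$dec1_w[] <- 0; m$params$dec2_w[] <- 0; m$params$dec3_w[] <- 0
  r0 <- decode_reconstruction(obj, 1, m)
  expect_equal(max(r0) - min(r0), 0)
})

test_that("margin loss matches the hand-evaluated hinge-squared cases", {
  # target slot underactivated
  expect_equal(margin_loss(c(0.5, 0, 0), c(1, 0, 0), m = 0.1), 0.16)
  # non-target slot overactivated
  expect_equal(margin_loss(c(0.95, 0.3), c(1, 0), m = 0.1),
               (0.3 - 0.1)^2)
  # both hinges inactive
  expect_equal(margin_loss(c(0.95, 0.05, 0.05), c(1, 0, 0), m = 0.1), 0)
  # class index form agrees with one-hot form
  expect_equal(margin_loss(c(0.2, 0.6), 2), margin_loss(c(0.2, 0.6), c(0, 1)))
})

test_that("margin loss is monotone in the slot norms, piecewise", {
  grid <- seq(0, 0.99, by = 0.03)
  target_losses <- vapply(grid, function(n)
    margin_loss(c(n, 0.05), c(1, 0)), numeric(1))
  expect_true(all(diff(target_losses) <= 1e-12))      # non-increasing
  nontarget_losses <- vapply(grid, function(n)
    margin_loss(c(0.95, n), c(1, 0)), numeric(1))
  expect_true(all(diff(nontarget_losses) >= -1e-12))  # non-decreasing
})

test_that("total loss combines class loss and weighted reconstruction MSE", {
  img <- matrix(0.5, 4, 4)
  rec <- matrix(0, 4, 4)      # MSE = 0.25
  expect_equal(total_loss(0.8, img, rec), 0.8 + 0.392 * 0.25)
  expect_equal(total_loss(0.8, img, rec), 0.898)
  expect_equal(total_loss(0.3, img, img), 0.3)
  expect_equal(total_loss(0.3, img, rec, loss_config(lambda_recon = 0)), 0.3)
  expect_error(total_loss(0.1, img, matrix(0, 3, 3)), "shape")

  set.seed(2)
  for (i in 1:5) {
    a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
    cl <- runif(1)
    expect_equal(total_loss(cl, a, b), cl + 0.392 * mean((a - b)^2),
                 tolerance = 1e-12)
  }
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(13)
  eps <- 1e-6
  # margin loss w.r.t. slot norms
  for (rep in 1:5) {
    norms <- runif(4, 0.02, 0.95)
    tgt <- as.numeric(seq_len(4) == sample(4, 1))
    an <- ora:::margin_loss_grad_norms(norms, tgt, 0.1)
    for (k in 1:4) {
      np <- norms; np[k] <- np[k] + eps
      nm <- norms; nm[k] <- nm[k] - eps
      fd <- (margin_loss(np, tgt) - margin_loss(nm, tgt)) / (2 * eps)
      expect_equal(an[k], fd, tolerance = 1e-4)
    }
  }
  # total loss w.r.t. reconstruction pixels
  img <- matrix(runif(16), 4, 4)
  rec <- matrix(runif(16), 4, 4)
  lc <- loss_config()
  for (k in sample(16, 4)) {
    rp <- rec; rp[k] <- rp[k] + eps
    rm <- rec; rm[k] <- rm[k] - eps
    fd <- (total_loss(0, img, rp, lc) - total_loss(0, img, rm, lc)) / (2 * eps)
    an <- lc$lambda_recon * 2 * (rec[k] - img[k]) / 16
    expect_equal(an, fd, tolerance = 1e-4)
  }
})

test_that("network backward passes agree with finite differences", {
  set.seed(21)
  cfg <- ora_config(image_size = 12, n_classes = 3, d_object = 4,
                    decoder_hidden = c(7, 8), seed = 5)
  m <- ora_model(cfg); m$kind <- "ora"
  xb <- array(runif(2 * 144), c(2, 12, 12, 1))
  yb1 <- c(1L, 3L)
  targ <- xb; dim(targ) <- c(2, 144)
  lc <- loss_config()
  res <- ora:::ora_batch_grads(m, xb, yb1, targ, lc)
  lossfun <- function(params) {
    m2 <- m; m2$params <- params
    ora:::ora_batch_grads(m2, xb, yb1, targ, lc)$loss
  }
  eps <- 1e-5
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (k in idx) {
      p1 <- m$params; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- m$params; p2[[nm]][k] <- p2[[nm]][k] - eps
      fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      an <- res$grads[[nm]][k]
      expect_equal(an, fd, tolerance = 1e-3,
                   label = sprintf("grad %s[%d] (analytic %.3g vs fd %.3g)",
                                   nm, k, an, fd))
    }
  }
})

test_that("spatial-frequency filter keeps/removes DC and matches its transfer function", {
  const <- matrix(0.7, 28, 28)
  lp <- filter_spatial_frequency(const, "low", 6, rescale = FALSE)
  expect_equal(lp, const, tolerance = 1e-10)
  hp <- filter_spatial_frequency(const, "high", 30, rescale = FALSE)
  expect_lt(max(abs(hp)), 1e-10)           # zero energy before rescale
  expect_error(filter_spatial_frequency(const, "low", 0), "positive")

  # single-frequency grating at 20 cycles/image (on a 64-pixel grid, well
  # below Nyquist): attenuation equals the Gaussian gain at rho = 20,
  # cross-checked against a hard FFT-mask oracle
  n <- 64
  gr <- matrix(sin(2 * pi * 20 * (col(matrix(0, n, n)) - 1) / n), n, n)
  amp_at <- function(img, cyc) {
    sp <- Mod(stats::fft(img)) / n^2
    sp[1, cyc + 1]
  }
  a0 <- amp_at(gr, 20)
  a_lp <- amp_at(filter_spatial_frequency(gr, "low", 6, rescale = FALSE), 20)
  a_hp <- amp_at(filter_spatial_frequency(gr, "high", 30, rescale = FALSE), 20)
  expect_equal(a_lp / a0, exp(-20^2 / (2 * 6^2)), tolerance = 1e-6)
  expect_equal(a_hp / a0, 1 - exp(-20^2 / (2 * 30^2)), tolerance = 1e-6)
  # low-pass at 6 suppresses the 20-cycle grating far more than the
  # high-pass at 30 does
  expect_lt(a_lp, a_hp)
  # oracle: a boolean FFT ring mask keeping >= 10 cycles retains the grating
  mask_keep_high <- function(img) {
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    rho <- sqrt(outer(k^2, k^2, "+"))
    Re(stats::fft(stats::fft(img) * (rho >= 10), inverse = TRUE)) / n^2
  }
  expect_equal(amp_at(mask_keep_high(gr), 20), a0, tolerance = 1e-10)
})

test_that("trainable parameter totals match the published model cards", {
  expect_equal(count_parameters(ora_model(ora_config())), 2904720)
  bl <- ora:::baseline_model(ora_config())
  expect_equal(count_parameters(bl), 1199882)
  expect_lt(count_parameters(bl), count_parameters(ora_model(ora_config())))
  # a dense map d_in = 8 -> d_out = 16 with bias
  expect_equal(count_parameters(list(params = list(w = matrix(0, 8, 16),
                                                   b = numeric(16)))), 144)
})

test_that("encode and decode shapes round-trip for both presets", {
  for (enc in c("small_cnn", "resnet18_small")) {
    m <- ora_model(ora_config(encoder = enc, seed = 4))
    f <- encode_feature_slots(matrix(runif(784), 28, 28), m)
    expect_equal(dim(f), c(m$config$n_feature_slots, 8))
    v <- compute_votes(f, m)
    expect_equal(dim(v), c(m$config$n_feature_slots, 10, 16))
    obj <- squash(matrix(rnorm(160), 10, 16))
    expect_equal(dim(decode_reconstruction(obj, 4, m)), c(28, 28))
  }
})
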