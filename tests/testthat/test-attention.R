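test_that("spatial masks threshold reconstructions at the configured intensity", {
  rec <- matrix(c(0.05, 0.2, 0.1, 0.09), 2, 2)
  m <- make_spatial_mask(rec, 0.1)
  expect_equal(as.vector(m), c(0, 1, 1, 0))   # at-threshold pixels survive
  expect_true(all(make_spatial_mask(rec, 0) == 1))
  expect_true(all(make_spatial_mask(rec, 0.5) == 0))
})

test_that("masking zeroes excluded pixels and renormalizes the survivors", {
  src <- matrix(c(0.2, 0.6, 0.9), 1, 3)
  msk <- matrix(c(0, 1, 1), 1, 3)
  expect_equal(apply_spatial_mask(src, msk), matrix(c(0, 0, 1), 1, 3))
  # already-spanning source under an all-ones mask is unchanged
  src2 <- matrix(seq(0, 1, length.out = 9), 3, 3)
  expect_equal(apply_spatial_mask(src2, matrix(1, 3, 3)), src2,
               tolerance = 1e-12)
  expect_equal(apply_spatial_mask(src2, matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_error(apply_spatial_mask(src2, matrix(1, 2, 2)), "shape")
  # custom bounds
  out <- apply_spatial_mask(src, msk, lb = 0.5, ub = 1)
  expect_equal(out, matrix(c(0, 0.5, 1), 1, 3))
})

test_that("reaction time is the first step below the entropy threshold, else the cap", {
  blank <- matrix(0.5, 8, 8)
  img <- matrix(runif(64), 8, 8)
  # scripted: uniform (not confident) for k-1 steps, then confident
  for (k in 1:5) {
    script <- c(rep(list(list(scores = uniform_scores(), recon = blank)),
                    k - 1),
                list(list(scores = onehot_scores(4), recon = blank)))
    tr <- recognize(img, stub_model(script))
    expect_equal(tr$rt_steps, k)
    expect_equal(tr$final_prediction, if (k == 1) 4L else 4L)
    expect_equal(tr$rt_steps,
                 min(which(tr$entropies < 0.6), inference_config()$max_steps))
  }
  # never confident: all five steps run, step-5 hypothesis returned
  script <- list(list(scores = c(2, 1, rep(1, 8)), recon = blank))
  tr5 <- recognize(img, stub_model(script))
  expect_equal(tr5$rt_steps, 5L)
  expect_equal(tr5$final_prediction, 1L)
  expect_true(all(tr5$entropies >= 0.6))
  expect_false(tr5$confident)
})

test_that("spatial ablation forces a single forward pass", {
  img <- matrix(runif(64), 8, 8)
  script <- list(list(scores = uniform_scores(), recon = matrix(0.5, 8, 8)))
  tr <- recognize(img, stub_model(script),
                  inference_config(spatial_enabled = FALSE))
  expect_equal(tr$rt_steps, 1L)
  expect_null(tr$steps[[1]]$mask)
})

test_that("masked-out pixels are exactly zero in every later input", {
  img <- matrix(runif(64, 0.2, 1), 8, 8)
  recon <- matrix(0, 8, 8); recon[3:6, 3:6] <- 0.9   # mask keeps a block
  script <- list(list(scores = uniform_scores(), recon = recon),
                 list(scores = uniform_scores(), recon = recon),
                 list(scores = onehot_scores(2), recon = recon))
  tr <- recognize(img, stub_model(script))
  expect_equal(tr$rt_steps, 3L)
  for (s in 2:3) {
    x <- tr$steps[[s]]$input_used
    expect_true(all(x[recon < 0.1] == 0))
    expect_true(any(x[3:6, 3:6] > 0))
  }
})

test_that("an all-zero mask falls back to the previous input", {
  img <- matrix(runif(64), 8, 8)
  dark <- matrix(0.01, 8, 8)                 # every pixel below threshold
  script <- list(list(scores = uniform_scores(), recon = dark),
                 list(scores = onehot_scores(7), recon = dark))
  tr <- recognize(img, stub_model(script))
  expect_true(tr$steps[[1]]$mask_fallback)
  expect_identical(tr$steps[[2]]$input_used, img)
})

test_that("recognition is deterministic and ablations match the plain classifier", {
  fit <- shared_fit()
  sp <- shared_glyphs()
  img <- sp$test$images[3, , ]
  t1 <- recognize(img, fit$model)
  t2 <- recognize(img, fit$model)
  expect_identical(t1, t2)

  # (-spatial, -binding) equals the plain training-time classifier
  cfg_off <- inference_config(spatial_enabled = FALSE,
                              binding_enabled = FALSE)
  n <- 30
  xs <- sp$test$images[seq_len(n), , , drop = FALSE]
  plain <- max.col(plain_class_scores(fit, xs), "first") - 1L
  preds <- predict(fit, xs, type = "class", cfg = cfg_off)
  expect_identical(preds, plain)
  rts <- predict(fit, xs, type = "rt", cfg = cfg_off)
  expect_true(all(rts == 1L))
  # and the per-image scores agree with the batch path numerically
  sc1 <- recognize(xs[1, , ], fit$model, cfg_off)$steps[[1]]$scores
  expect_equal(sc1, as.vector(plain_class_scores(fit, xs[1, , ])),
               tolerance = 1e-10)
})

test_that("untrained models are rejected by the attention loop", {
  m <- ora_model(ora_config(image_size = 12, n_classes = 3, d_object = 4,
                            decoder_hidden = c(5, 6)))
  expect_error(recognize(matrix(0.5, 12, 12), m), "trained")
})

test_that("spatial masking can only help recover from a wrong first hypothesis", {
  fit <- shared_fit()
  sp <- shared_glyphs()
  cor_on <- inference_config()
  cor_off <- inference_config(spatial_enabled = FALSE)
  rec_on <- c(); rec_off <- c()
  for (ds in 0:2) {
    x <- corrupt_batch(sp$test$images[1:20, , , drop = FALSE],
                       corruption_spec("gaussian_noise", 4, seed = ds))
    y <- sp$test$labels[1:20]
    for (i in 1:20) {
      t_on <- recognize(x[i, , ], fit$model, cor_on)
      if (t_on$hypotheses[1] - 1L != y[i]) {
        rec_on <- c(rec_on, t_on$final_prediction - 1L == y[i])
        t_off <- recognize(x[i, , ], fit$model, cor_off)
        # without masking the first hypothesis is final: recovery impossible
        rec_off <- c(rec_off, t_off$final_prediction != t_off$hypotheses[1])
      }
    }
  }
  expect_true(length(rec_on) > 0)
  expect_true(all(!rec_off))
  expect_gte(mean(rec_on), mean(rec_off))
})

test_that("sequential recognition explains away disjoint glyphs one at a time", {
  img <- matrix(0, 8, 8)
  img[1:3, 1:3] <- 0.9         # object A support
  img[6:8, 6:8] <- 0.8         # object B support
  reconA <- matrix(0, 8, 8); reconA[1:3, 1:3] <- 0.9
  reconB <- matrix(0, 8, 8); reconB[6:8, 6:8] <- 0.8
  # stub recognizes A while its pixels are present, else B
  model <- list(config = list(n_classes = 10, image_size = 8),
                step_fn = function(image, step) {
                  if (sum(image[1:3, 1:3]) > 0)
                    list(scores = onehot_scores(1), reconstruction = reconA)
                  else
                    list(scores = onehot_scores(2), reconstruction = reconB)
                })
  sq <- recognize_sequence(img, model, n_objects = 2)
  expect_equal(sq$predictions, c(1L, 2L))
  expect_equal(sq$n_confident, 2L)
  expect_equal(sq$rt_total, 2L)
  # after the first object is explained away, the second's pixels survive
  expect_equal(sq$passes[[2]]$input_used[6:8, 6:8], img[6:8, 6:8])
  expect_true(all(sq$passes[[2]]$input_used[1:3, 1:3] == 0))
  expect_error(recognize_sequence(img, model, n_objects = 0), "n_objects")
})

test_that("a never-confident sequential search stops at the pass budget", {
  img <- matrix(runif(64), 8, 8)
  model <- list(config = list(n_classes = 10, image_size = 8),
                step_fn = function(image, step)
                  list(scores = c(3, 2, rep(1, 8)),
                       reconstruction = matrix(0.5, 8, 8)))
  sq <- recognize_sequence(img, model, max_iters = 10, n_objects = 2)
  expect_equal(sq$rt_total, 10L)
  expect_equal(length(sq$predictions), 2L)
  expect_equal(sq$n_confident, 0L)
  expect_true(all(sq$forced))
  # distinct classes, ordered by the scripted score ranking
  expect_equal(sort(sq$predictions), c(1L, 2L))
})

test_that("traces serialize to JSON with per-step scalars", {
  blank <- matrix(0.5, 8, 8)
  tr <- recognize(matrix(runif(64), 8, 8),
                  stub_model(list(list(scores = onehot_scores(3),
                                       recon = blank))))
  js <- trace_to_json(tr)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$rt_steps, 1)
  expect_equal(parsed$final_prediction, 3)
  expect_equal(parsed$steps$hypothesis, 3)
  f <- file.path(tempdir(), "trace.json")
  trace_to_json(tr, f)
  expect_true(file.exists(f))
  unlink(f)
})
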