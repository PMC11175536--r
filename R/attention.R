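# The inference-time attention loop: up to max_steps forward passes, each
# followed (if confidence is not reached) by thresholding the current best
# object reconstruction into a boolean spatial mask that suppresses input
# pixels outside the hypothesized object shape on the next pass.

#' Inference configuration
#'
#' @param max_steps Maximum forward processing steps (default 5).
#' @param entropy_threshold Stopping entropy in nats (default 0.6).
#' @param mask_threshold Reconstruction intensity threshold for the spatial
#'   mask (default 0.1, the MNIST-scale value; 0.05 is the documented
#'   ImageNet-scale constant).
#' @param mask_target What the mask multiplies: the original `"input"`
#'   (default: input evidence survives masking) or the model's own
#'   `"reconstruction"`.
#' @param renorm_lb,renorm_ub MaxMin bounds for renormalizing the masked-in
#'   pixels.
#' @param spatial_enabled,binding_enabled Ablation switches; with spatial
#'   masking off exactly one forward pass runs.
#' @param n_binding_iter Binding iterations per forward step (default 3).
#' @param confidence_source `"auto"` feeds the adjusted likelihood to the
#'   stopping entropy when binding is enabled and the raw slot norms when it
#'   is ablated; `"adjusted"`/`"raw"` force one or the other.
#' @return A list of class `ora_infer_config`.
#' @export
inference_config <- function(max_steps = 5, entropy_threshold = 0.6,
                             mask_threshold = 0.1,
                             mask_target = c("input", "reconstruction"),
                             renorm_lb = 0, renorm_ub = 1,
                             spatial_enabled = TRUE, binding_enabled = TRUE,
                             n_binding_iter = 3,
                             confidence_source = c("auto", "adjusted", "raw")) {
  stopifnot(max_steps >= 1, mask_threshold > 0, mask_threshold < 1)
  structure(list(max_steps = as.integer(max_steps),
                 entropy_threshold = entropy_threshold,
                 mask_threshold = mask_threshold,
                 mask_target = match.arg(mask_target),
                 renorm_lb = renorm_lb, renorm_ub = renorm_ub,
                 spatial_enabled = spatial_enabled,
                 binding_enabled = binding_enabled,
                 n_binding_iter = as.integer(n_binding_iter),
                 confidence_source = match.arg(confidence_source)),
            class = "ora_infer_config")
}

#' Threshold a reconstruction into a boolean spatial mask
#'
#' @param reconstruction Image matrix in `[0, 1]`.
#' @param threshold Intensity threshold; pixels at or above it are masked in
#'   (1), pixels below are masked out (0).
#' @return A 0/1 matrix of the same shape.
#' @export
make_spatial_mask <- function(reconstruction, threshold = 0.1) {
  (reconstruction >= threshold) * 1
}

#' Apply a spatial mask and renormalize the surviving pixels
#'
#' Multiplies the source image by the boolean mask, then MaxMin-renormalizes
#' the masked-in (non-zero-mask) region into `[lb, ub]`. Masked-out pixels
#' stay exactly zero.
#'
#' @param source Image matrix.
#' @param mask 0/1 matrix of the same shape.
#' @param lb,ub Renormalization bounds.
#' @return Masked, renormalized image matrix.
#' @export
apply_spatial_mask <- function(source, mask, lb = 0, ub = 1) {
  if (!all(dim(source) == dim(mask)))
    stop("source and mask must have identical shape")
  out <- source * mask
  nz <- mask > 0
  if (any(nz)) out[nz] <- maxmin_normalize(out[nz], lb, ub)
  out
}

# One forward pass: returns the confidence-source scores, the best-class
# reconstruction, and bookkeeping. A model may carry a $step_fn(image, step)
# hook returning list(scores, reconstruction) — used for scripted stub
# models when testing the loop contract in isolation.
forward_step <- function(model, image, cfg, step) {
  if (!is.null(model$step_fn)) {
    res <- model$step_fn(image, step)
    return(list(scores = res$scores, reconstruction = res$reconstruction,
                binding = NULL))
  }
  if (!isTRUE(model$trained))
    stop("model has no trained weights; fit it with ora() first")
  bind <- run_feature_binding(model, image, n_iter = cfg$n_binding_iter,
                              enabled = cfg$binding_enabled)
  src <- switch(cfg$confidence_source,
                auto = if (cfg$binding_enabled) "adjusted" else "raw",
                cfg$confidence_source)
  scores <- bind$scores[[src]]
  hyp <- which.max(scores)
  s <- model$config$image_size
  list(scores = scores,
       reconstruction = matrix(bind$reconstructions[hyp, ], s, s),
       binding = bind)
}

#' Recognize an image with reconstruction-guided attention
#'
#' Runs up to `max_steps` forward passes. After each pass the classification
#' entropy is compared with the threshold; if the model is not yet confident,
#' the reconstruction of its current best hypothesis is thresholded into a
#' spatial mask which is applied to the mask target (the original input by
#' default) to form the next pass's input. If a mask would zero the whole
#' image, masking is skipped for that step and the previous input is reused.
#' The number of forward passes executed is the model's reaction time.
#'
#' @param image Input image matrix in `[0, 1]`.
#' @param model A fitted model (the `$model` of an `ora_fit`, or an
#'   `ora_fit` itself).
#' @param cfg An [inference_config()].
#' @return A list of class `ora_trace`: per-step records (`input_used`,
#'   `reconstruction`, `mask`, `scores`, `entropy`, `hypothesis`,
#'   `mask_fallback`), `entropies`, `hypotheses`, `rt_steps`,
#'   `final_prediction` (1-based class index), `confident`.
#' @export
recognize <- function(image, model, cfg = inference_config()) {
  if (inherits(model, "ora_fit")) model <- model$model
  steps <- list()
  x <- image
  rt <- 0L
  repeat {
    rt <- rt + 1L
    fw <- forward_step(model, x, cfg, rt)
    conf <- confidence(fw$scores, cfg$entropy_threshold)
    hyp <- which.max(fw$scores)
    rec <- list(input_used = x, reconstruction = fw$reconstruction,
                mask = NULL, scores = fw$scores, entropy = conf$entropy,
                hypothesis = hyp, mask_fallback = FALSE,
                binding_iterations = if (!is.null(fw$binding))
                  fw$binding$iterations)
    if (conf$confident || rt >= cfg$max_steps || !cfg$spatial_enabled) {
      steps[[rt]] <- rec
      break
    }
    mask <- make_spatial_mask(fw$reconstruction, cfg$mask_threshold)
    rec$mask <- mask
    if (all(mask == 0)) {
      rec$mask_fallback <- TRUE          # blank mask: reuse previous input
    } else {
      src <- if (cfg$mask_target == "input") image else fw$reconstruction
      x <- apply_spatial_mask(src, mask, cfg$renorm_lb, cfg$renorm_ub)
    }
    steps[[rt]] <- rec
  }
  structure(list(
    steps = steps,
    entropies = vapply(steps, `[[`, numeric(1), "entropy"),
    hypotheses = vapply(steps, `[[`, integer(1), "hypothesis"),
    rt_steps = rt,
    final_prediction = steps[[rt]]$hypothesis,
    confident = conf$confident
  ), class = "ora_trace")
}

#' Sequential recognition of multiple overlapping objects
#'
#' Applies the attention loop repeatedly: once an object is recognized with
#' entropy below `seq_entropy`, the mask of its reconstruction is inverted
#' and applied to the working image so that processing continues on the
#' input signals left unexplained, and recognition restarts for the next
#' object. Each object gets at most `steps_per_object` forward passes; if
#' confidence is not reached within that budget the most confident (lowest
#' entropy) hypothesis seen for the object is accepted and its
#' reconstruction mask removed, so the search can move on. Stops after
#' `n_objects` identities or `max_iters` total forward passes; any remaining
#' slots are filled with the lowest-entropy hypotheses observed (distinct
#' classes).
#'
#' @param image Input image matrix (canvas must match the model's
#'   `image_size`).
#' @param model Fitted model or `ora_fit`.
#' @param cfg An [inference_config()]; its mask parameters are reused.
#' @param max_iters Total forward-pass budget (default 10).
#' @param seq_entropy Confidence threshold in nats for accepting an object
#'   (default 1.0).
#' @param n_objects Number of objects to report (default 2).
#' @param steps_per_object Forward-pass budget per object (default 5).
#' @return A list of class `ora_seq`: `predictions` (class indices, length
#'   `n_objects`), `n_confident` (objects accepted below threshold),
#'   `forced` (per found object, whether acceptance was forced by the step
#'   budget), `passes` (per-pass records), `rt_total`.
#' @export
recognize_sequence <- function(image, model, cfg = inference_config(),
                               max_iters = 10, seq_entropy = 1.0,
                               n_objects = 2, steps_per_object = 5) {
  if (n_objects < 1) stop("n_objects must be >= 1")
  if (inherits(model, "ora_fit")) model <- model$model
  working <- image            # evidence not yet explained by found objects
  found <- integer(0)
  found_forced <- logical(0)
  passes <- list()
  t <- 0L
  while (t < max_iters && length(found) < n_objects) {
    x <- working
    obj <- list()             # passes spent on the current object
    repeat {
      t <- t + 1L
      fw <- forward_step(model, x, cfg, t)
      sc <- fw$scores
      sc[found] <- 0          # already-explained classes cannot be the next object
      conf <- confidence(sc, seq_entropy)
      hyp <- which.max(sc)
      if (hyp != which.max(fw$scores) && !is.null(fw$binding)) {
        # use the reconstruction of the excluded-argmax hypothesis
        s <- model$config$image_size
        fw$reconstruction <- matrix(fw$binding$reconstructions[hyp, ], s, s)
      }
      mask <- make_spatial_mask(fw$reconstruction, cfg$mask_threshold)
      rec <- list(hypothesis = hyp, entropy = conf$entropy,
                  scores = sc, input_used = x,
                  reconstruction = fw$reconstruction, mask = mask,
                  accepted = conf$confident)
      passes[[t]] <- rec
      obj[[length(obj) + 1L]] <- rec
      if (conf$confident) {
        found <- c(found, hyp); found_forced <- c(found_forced, FALSE)
        working <- working * (1 - mask)   # explain away the found object
        break
      }
      if (length(obj) >= steps_per_object || t >= max_iters) {
        # step budget exhausted: accept the most confident hypothesis seen
        # for this object and move on
        best <- obj[[which.min(vapply(obj, `[[`, numeric(1), "entropy"))]]
        found <- c(found, best$hypothesis)
        found_forced <- c(found_forced, TRUE)
        working <- working * (1 - best$mask)
        break
      }
      # not confident yet: focus on the current hypothesis within the
      # unexplained evidence
      if (any(mask > 0))
        x <- apply_spatial_mask(working, mask, cfg$renorm_lb, cfg$renorm_ub)
    }
  }
  preds <- found
  if (length(preds) < n_objects) {
    ord <- order(vapply(passes, `[[`, numeric(1), "entropy"))
    for (i in ord) {
      h <- passes[[i]]$hypothesis
      if (!(h %in% preds)) preds <- c(preds, h)
      if (length(preds) >= n_objects) break
    }
    # still short (every pass agreed): take runner-up classes from the most
    # confident pass
    if (length(preds) < n_objects) {
      best <- passes[[ord[1]]]$scores
      for (h in order(best, decreasing = TRUE)) {
        if (!(h %in% preds)) preds <- c(preds, h)
        if (length(preds) >= n_objects) break
      }
    }
  }
  structure(list(predictions = preds[seq_len(n_objects)],
                 n_confident = sum(!found_forced),
                 forced = found_forced,
                 passes = passes, rt_total = t),
            class = "ora_seq")
}

#' Serialize an episode trace to JSON
#'
#' Writes the per-step scalars of a recognition trace (entropy, hypothesis,
#' class scores, mask fallback flag) plus the reaction time and final
#' prediction. Image panels are intentionally not embedded; use
#' [plot.ora_trace()] for those.
#'
#' @param trace An `ora_trace`.
#' @param path Output file; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
trace_to_json <- function(trace, path = NULL) {
  obj <- list(
    rt_steps = trace$rt_steps,
    final_prediction = trace$final_prediction,
    confident = trace$confident,
    steps = lapply(trace$steps, function(s) list(
      entropy = s$entropy, hypothesis = s$hypothesis,
      scores = as.numeric(s$scores), mask_fallback = s$mask_fallback))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Plot a recognition trace as an image strip
#'
#' Draws, for each forward processing step, the input used, the best-class
#' reconstruction, and the spatial mask (when one was generated), annotated
#' with the step's hypothesis and entropy.
#'
#' @param x An `ora_trace`.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.ora_trace <- function(x, ...) {
  ns <- length(x$steps)
  op <- graphics::par(mfrow = c(3, ns), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  draw <- function(img, main) {
    if (is.null(img)) {
      graphics::plot.new(); graphics::title(main)
    } else {
      graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(64, 0, 1),
                      axes = FALSE, main = main, zlim = c(0, 1))
    }
  }
  for (s in seq_len(ns))
    draw(x$steps[[s]]$input_used,
         sprintf("step %d: class %d\nH=%.2f", s, x$steps[[s]]$hypothesis - 1,
                 x$steps[[s]]$entropy))
  for (s in seq_len(ns)) draw(x$steps[[s]]$reconstruction, "reconstruction")
  for (s in seq_len(ns)) draw(x$steps[[s]]$mask, "mask")
  invisible(x)
}
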