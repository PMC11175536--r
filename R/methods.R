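# S3 methods for fitted models.

#' @export
print.ora_fit <- function(x, ...) {
  cfg <- x$model$config
  cat(sprintf("%s model (%s encoder), %d classes, %dx%d input\n",
              if (x$model_kind == "ora") "Reconstruction-guided attention"
              else "CNN baseline",
              cfg$encoder, cfg$n_classes, cfg$image_size, cfg$image_size))
  if (x$model_kind == "ora")
    cat(sprintf("  %d feature slots (dim %d), %d object slots (dim %d)\n",
                cfg$n_feature_slots, cfg$d_feature, cfg$n_classes,
                cfg$d_object))
  cat(sprintf("  %s trainable parameters\n",
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  trained %d epoch(s); best validation accuracy %.3f (epoch %d)\n",
              nrow(x$history), x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
summary.ora_fit <- function(object, ...) {
  out <- list(fit = object, history = object$history,
              n_parameters = object$n_parameters,
              best_val_accuracy = object$best_val_accuracy)
  class(out) <- "summary.ora_fit"
  out
}

#' @export
print.summary.ora_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTraining history:\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' Predict classes with the full attention loop
#'
#' Runs [recognize()] per image for the slot model (one feed-forward pass
#' for the CNN baseline) and returns labels, probabilities, reaction times
#' or full traces.
#'
#' @param object An `ora_fit`.
#' @param newdata (N, S, S) array or a single image matrix.
#' @param type `"class"` (0-based labels), `"prob"` (stopping-step class
#'   probabilities), `"rt"` (forward steps taken), or `"trace"` (list of
#'   `ora_trace`).
#' @param cfg An [inference_config()].
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.ora_fit <- function(object, newdata,
                            type = c("class", "prob", "rt", "trace"),
                            cfg = inference_config(), ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  x <- if (single) array(newdata, c(1, dim(newdata))) else newdata
  n <- dim(x)[1]
  if (identical(object$model_kind, "cnn")) {
    sc <- plain_class_scores(object, x)
    out <- switch(type,
      class = max.col(sc, "first") - 1L,
      prob = t(apply(sc, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z))))),
      rt = rep(1L, n),
      trace = stop("traces are only available for the slot model"))
    return(if (single && type != "prob") out[1] else out)
  }
  traces <- lapply(seq_len(n), function(i) recognize(x[i, , ], object, cfg))
  out <- switch(type,
    class = vapply(traces, function(t) t$final_prediction - 1L, integer(1)),
    rt = vapply(traces, `[[`, integer(1), "rt_steps"),
    prob = t(vapply(traces, function(t)
      confidence(t$steps[[t$rt_steps]]$scores)$probabilities,
      numeric(object$model$config$n_classes))),
    trace = traces)
  if (single && type %in% c("class", "rt")) out[1] else out
}

#' Plot training history
#'
#' Training loss (left axis) and validation accuracy (right axis) per epoch.
#'
#' @param x An `ora_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ora_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss",
                 main = "Training history", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$val_accuracy, type = "b", pch = 1, lty = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("validation accuracy", side = 4, line = 2.5)
  invisible(x)
}

#' Residual reconstruction error of the fitted decoder
#'
#' For each image, the pixel residual between the input and the decoder's
#' reconstruction of the most activated object slot from a plain forward
#' pass (no attention iterations).
#'
#' @param object An `ora_fit` (slot model).
#' @param newdata (N, S, S) array or single image matrix.
#' @param ... Unused.
#' @return Array of residuals matching `newdata`'s shape.
#' @export
residuals.ora_fit <- function(object, newdata, ...) {
  if (identical(object$model_kind, "cnn"))
    stop("the CNN baseline has no reconstruction pathway")
  model <- object$model
  single <- is.matrix(newdata)
  x <- if (single) array(newdata, c(1, dim(newdata))) else newdata
  n <- dim(x)[1]
  out <- x
  for (i in seq_len(n)) {
    bind <- run_feature_binding(model, x[i, , ], n_iter = 1, enabled = FALSE)
    j <- which.max(bind$scores$raw)
    s <- model$config$image_size
    out[i, , ] <- x[i, , ] - matrix(bind$reconstructions[j, ], s, s)
  }
  if (single) out[1, , ] else out
}
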