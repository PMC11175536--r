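# Evaluation harness: per-corruption accuracy, reaction-time statistics,
# confusion matrices, hypothesis-change rates (across spatial-masking steps
# and across binding iterations, reported with both the all-trials and the
# initially-wrong-trials denominator), and difficulty bins.

#' Evaluate a model on (optionally corrupted) images
#'
#' Runs the full attention-loop recognition on every image under every
#' corruption in `corruptions` and aggregates accuracy, reaction time,
#' confusion and hypothesis-change statistics.
#'
#' @param model An `ora_fit` or trained `ora_model`. A CNN-baseline fit is
#'   evaluated as a single feed-forward pass.
#' @param images (N, S, S) array of clean images.
#' @param labels Integer labels, 0-based.
#' @param corruptions A list of [corruption_spec()]s (default: identity
#'   only).
#' @param cfg An [inference_config()].
#' @return An object of class `ora_eval`: named per-corruption reports, each
#'   with `accuracy`, `mean_rt`, `rt_hist`, `confusion`,
#'   `change` (hypothesis-change rates), `recovery_rate`,
#'   `bins` (short/medium/long counts) and `n`; plus an `overall` pooled
#'   summary.
#' @export
evaluate_model <- function(model, images, labels,
                           corruptions = list(corruption_spec("identity")),
                           cfg = inference_config()) {
  if (inherits(model, "ora_fit")) {
    if (identical(model$model_kind, "cnn"))
      return(evaluate_baseline(model, images, labels, corruptions))
    model <- model$model
  }
  n <- dim(images)[1]
  if (is.null(n) || n == 0) stop("empty dataset")
  labels <- as.integer(labels)
  no <- model$config$n_classes
  reports <- list()
  for (cs in corruptions) {
    x <- corrupt_batch(images, cs)
    rt <- integer(n); pred <- integer(n)
    first_hyp <- integer(n); sp_change <- logical(n); bi_change <- logical(n)
    for (i in seq_len(n)) {
      tr <- recognize(x[i, , ], model, cfg)
      rt[i] <- tr$rt_steps
      pred[i] <- tr$final_prediction - 1L
      first_hyp[i] <- tr$hypotheses[1] - 1L
      sp_change[i] <- length(unique(tr$hypotheses)) > 1
      bi_change[i] <- any(vapply(tr$steps, function(s) {
        it <- s$binding_iterations
        !is.null(it) && length(it) > 1 &&
          length(unique(vapply(it, `[[`, integer(1), "hypothesis"))) > 1
      }, logical(1)))
    }
    correct <- pred == labels
    wrong_start <- first_hyp != labels
    confusion <- table(factor(labels, levels = 0:(no - 1)),
                       factor(pred, levels = 0:(no - 1)))
    reports[[cs$kind]] <- list(
      kind = cs$kind, severity = cs$severity, n = n,
      accuracy = mean(correct),
      mean_rt = mean(rt),
      rt_hist = table(factor(rt, levels = seq_len(cfg$max_steps))),
      confusion = unclass(confusion),
      change = list(
        spatial_all = mean(sp_change),
        spatial_wrong_start = if (any(wrong_start))
          mean(sp_change[wrong_start]) else NA_real_,
        binding_all = mean(bi_change),
        binding_wrong_start = if (any(wrong_start))
          mean(bi_change[wrong_start]) else NA_real_),
      recovery_rate = if (any(wrong_start))
        mean(correct[wrong_start]) else NA_real_,
      bins = c(short = sum(rt == 1), medium = sum(rt %in% 2:3),
               long = sum(rt >= 4)),
      rt = rt, predictions = pred, labels = labels
    )
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  mrt <- vapply(reports, `[[`, numeric(1), "mean_rt")
  structure(list(per_corruption = reports,
                 overall = list(accuracy = mean(acc), mean_rt = mean(mrt)),
                 cfg = cfg),
            class = "ora_eval")
}

# Single-pass evaluation of the CNN baseline (reaction time is 1 by
# construction: it has no reconstruction feedback).
evaluate_baseline <- function(fit, images, labels, corruptions) {
  n <- dim(images)[1]
  labels <- as.integer(labels)
  no <- fit$model$config$n_classes
  reports <- list()
  for (cs in corruptions) {
    x <- corrupt_batch(images, cs)
    pred <- max.col(plain_class_scores(fit, x), "first") - 1L
    correct <- pred == labels
    reports[[cs$kind]] <- list(
      kind = cs$kind, severity = cs$severity, n = n,
      accuracy = mean(correct), mean_rt = 1,
      rt_hist = table(factor(rep(1, n), levels = 1:5)),
      confusion = unclass(table(factor(labels, levels = 0:(no - 1)),
                                factor(pred, levels = 0:(no - 1)))),
      change = list(spatial_all = 0, spatial_wrong_start = NA_real_,
                    binding_all = 0, binding_wrong_start = NA_real_),
      recovery_rate = NA_real_,
      bins = c(short = n, medium = 0L, long = 0L),
      rt = rep(1L, n), predictions = pred, labels = labels
    )
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  structure(list(per_corruption = reports,
                 overall = list(accuracy = mean(acc), mean_rt = 1),
                 cfg = NULL),
            class = "ora_eval")
}

#' Four-condition ablation suite
#'
#' Evaluates the model with spatial masking and feature binding each enabled
#' or ablated, on identical corrupted inputs, mirroring the
#' accuracy-and-reaction-time ablation comparison.
#'
#' @param model `ora_fit` or trained `ora_model`.
#' @param images,labels Evaluation set (labels 0-based).
#' @param corruptions List of [corruption_spec()]s.
#' @param cfg Base [inference_config()]; the ablation switches are
#'   overridden per condition.
#' @return An object of class `ora_ablation`: the four `ora_eval` reports
#'   (`full`, `no_spatial`, `no_binding`, `none`) and a `comparison` data
#'   frame (condition, accuracy, mean_rt).
#' @export
ablation_suite <- function(model, images, labels,
                           corruptions = list(corruption_spec("identity")),
                           cfg = inference_config()) {
  conditions <- list(
    full       = c(spatial = TRUE,  binding = TRUE),
    no_spatial = c(spatial = FALSE, binding = TRUE),
    no_binding = c(spatial = TRUE,  binding = FALSE),
    none       = c(spatial = FALSE, binding = FALSE)
  )
  results <- list()
  for (nm in names(conditions)) {
    ci <- cfg
    ci$spatial_enabled <- conditions[[nm]][["spatial"]]
    ci$binding_enabled <- conditions[[nm]][["binding"]]
    results[[nm]] <- evaluate_model(model, images, labels, corruptions, ci)
  }
  comparison <- data.frame(
    condition = names(conditions),
    accuracy = vapply(results, function(r) r$overall$accuracy, numeric(1)),
    mean_rt = vapply(results, function(r) r$overall$mean_rt, numeric(1)),
    row.names = NULL
  )
  structure(list(results = results, comparison = comparison),
            class = "ora_ablation")
}

#' @export
print.ora_eval <- function(x, ...) {
  cat("Recognition evaluation\n")
  for (r in x$per_corruption) {
    cat(sprintf("  %-14s (sev %d, n=%d): accuracy %.3f, mean RT %.2f steps\n",
                r$kind, r$severity, r$n, r$accuracy, r$mean_rt))
    cat(sprintf("    bins short/medium/long: %d/%d/%d",
                r$bins["short"], r$bins["medium"], r$bins["long"]))
    if (!is.na(r$recovery_rate))
      cat(sprintf("; recovery from wrong start: %.2f", r$recovery_rate))
    cat("\n")
  }
  cat(sprintf("  overall: accuracy %.3f, mean RT %.2f\n",
              x$overall$accuracy, x$overall$mean_rt))
  invisible(x)
}

#' @export
print.ora_ablation <- function(x, ...) {
  cat("Ablation suite (+/- spatial masking, +/- feature binding)\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}
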