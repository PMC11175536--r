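# Reconstruction-guided feature binding: three inference-time iterations
# that reweight the feature->object votes by the product of a vote/object
# similarity score (b) and a per-class reconstruction score (r). Runs per
# image, without gradient tracking; coefficients are never learned.

#' Run reconstruction-guided feature binding
#'
#' Performs the inference-time binding iterations for one image. Per
#' iteration: object slots are aggregated from coefficient-weighted votes
#' and squashed; the similarity score `b` accumulates vote-object dot
#' products and is MaxMin-normalized over objects with a 0.5 floor; every
#' class slot is decoded and scored by the negative MSE between its
#' reconstruction and the current input; that score is broadcast over
#' features, MaxMin-normalized over objects with a 0.5 floor into `r`; the
#' binding coefficients are `c = b * r`. After the final iteration the
#' object slots are re-aggregated with the final coefficients, all classes
#' are decoded once more, and the class likelihood is adjusted by the
#' reconstruction score. With `enabled = FALSE` (the ablation) the
#' coefficients stay 1, a single aggregation is performed, and the adjusted
#' likelihood equals the raw slot norms.
#'
#' @param model An [ora_model()] (or fitted `ora_fit`'s `$model`).
#' @param image Current input image matrix (possibly masked), in `[0, 1]`.
#' @param features Optional pre-computed squashed feature-slot matrix
#'   (`n_feature_slots` x `d_feature`); encoded from `image` when NULL.
#' @param n_iter Number of binding iterations (default 3).
#' @param enabled Set FALSE to ablate feature binding.
#' @return A list of class `ora_binding`: `objects` (final squashed object
#'   slots, classes x d_object), `state` (matrices `c`, `b`, `r`, each
#'   feature x object), `scores` (raw norms, recon_score = -MSE, adjusted,
#'   and the argmax `hypothesis`), `reconstructions` (classes x pixels from
#'   the final slots), and `iterations` (per-iteration norms, mapped
#'   reconstruction scores and hypothesis).
#' @export
run_feature_binding <- function(model, image, features = NULL, n_iter = 3,
                                enabled = TRUE) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  cfg <- model$config
  no <- cfg$n_classes; do_ <- cfg$d_object; nf <- cfg$n_feature_slots
  if (is.null(features)) features <- encode_feature_slots(image, model)
  imgvec <- as.vector(image)
  fflat <- as.vector(t(features))               # slot-major, dim fastest

  cmat <- matrix(1, nf, no)
  bmat <- matrix(0, nf, no)
  rmat <- matrix(0, nf, no)
  iterations <- list()

  if (enabled) {
    v <- votes_matrix(features, model)          # nf x (no*do)
    va <- v; dim(va) <- c(nf, do_, no)          # [i, d, j] for dot products
    jexp <- rep(seq_len(no), each = do_)
    for (t in seq_len(n_iter)) {
      s <- colSums(v * cmat[, jexp])            # weighted aggregation
      osq <- squash_rows(matrix(s, no, do_, byrow = TRUE))
      for (j in seq_len(no))
        bmat[, j] <- bmat[, j] + va[, , j] %*% osq[j, ]
      bmat <- pmax(maxmin_normalize(bmat, 0, 1, axis = 1), 0.5)
      oflat <- as.vector(t(osq))
      recons <- decode_all_classes(model$params, oflat, no, do_)
      mse <- rowMeans(sweep(recons, 2, imgvec)^2)
      mapped_r <- pmax(maxmin_normalize(-mse, 0, 1), 0.5)
      rmat <- matrix(mapped_r, nf, no, byrow = TRUE)
      cmat <- bmat * rmat
      norms_t <- sqrt(rowSums(osq^2))
      adj_t <- norms_t * maxmin_normalize(-mse, 0, 1)
      iterations[[t]] <- list(norms = norms_t, mapped_r = mapped_r,
                              hypothesis = which.max(adj_t))
    }
    s <- colSums(v * cmat[, jexp])              # final re-aggregation
  } else {
    s <- as.vector(fflat %*% model$params$vote_w)
  }
  osq <- squash_rows(matrix(s, no, do_, byrow = TRUE))
  raw <- sqrt(rowSums(osq^2))
  recons <- decode_all_classes(model$params, as.vector(t(osq)), no, do_)
  recon_score <- -rowMeans(sweep(recons, 2, imgvec)^2)
  scores <- list(raw = raw, recon_score = recon_score)
  scores$adjusted <- if (enabled) adjusted_likelihood(scores) else raw
  scores$hypothesis <- which.max(scores$adjusted)
  structure(list(
    objects = osq,
    state = list(c = cmat, b = bmat, r = rmat, n_iter = n_iter,
                 enabled = enabled),
    scores = scores,
    reconstructions = recons,
    iterations = iterations
  ), class = "ora_binding")
}

#' Reconstruction-adjusted class likelihood
#'
#' Maps the per-class reconstruction scores (negative MSE) into `[0, 1]` by
#' MaxMin normalization over classes and multiplies them into the raw slot
#' norms. The argmax of the adjusted likelihood is the model's current
#' hypothesis; when reconstruction scores do not discriminate (degenerate
#' normalization maps them all to 1) the adjusted likelihood equals the raw
#' norms.
#'
#' @param scores A list with elements `raw` (slot norms) and `recon_score`
#'   (negative per-class reconstruction MSE), e.g. the `scores` element of
#'   [run_feature_binding()].
#' @return Numeric vector of adjusted likelihoods, same length as `raw`.
#' @export
adjusted_likelihood <- function(scores) {
  mapped <- maxmin_normalize(scores$recon_score, 0, 1)
  scores$raw * mapped
}

#' Write binding-state matrices to CSV
#'
#' Exports the `c`, `b` and `r` coefficient matrices of a binding result to
#' `<prefix>_c.csv`, `<prefix>_b.csv`, `<prefix>_r.csv` for coefficient
#' heat-map inspection.
#'
#' @param binding An `ora_binding` result.
#' @param prefix File path prefix.
#' @return Invisibly, the written file names.
#' @export
write_binding_csv <- function(binding, prefix) {
  files <- character(3)
  for (i in seq_along(c("c", "b", "r"))) {
    nm <- c("c", "b", "r")[i]
    files[i] <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(binding$state[[nm]], files[i], row.names = FALSE)
  }
  invisible(files)
}
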