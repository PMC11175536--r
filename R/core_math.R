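#' Squash nonlinearity for slot vectors
#'
#' Maps each vector \code{v} to \code{(||v||^2 / (1 + ||v||^2)) * v / ||v||}:
#' the direction is preserved and the norm is compressed into \code{[0, 1)},
#' so a slot's vector magnitude can be read as the probability that the
#' entity it represents is present. The zero vector maps exactly to the zero
#' vector (the continuity limit, implemented with an explicit guard); a small
#' epsilon stabilises the gradient near zero during training.
#'
#' @param v A numeric vector (one slot) or a matrix whose rows are slot
#'   vectors.
#' @param eps Numerical guard added under the square root of the norm.
#' @return An object of the same shape as \code{v} with every vector norm
#'   strictly below 1.
#' @examples
#' squash(c(3, 4))            # norm 25/26, direction (0.6, 0.8)
#' squash(c(1, 0))            # a unit vector halves: (0.5, 0)
#' @export
squash <- function(v, eps = 1e-8) {
  if (!all(is.finite(v))) stop("squash: input must be finite")
  if (is.matrix(v)) return(squash_rows(v, eps))
  n2 <- sum(v^2)
  if (n2 == 0) return(v * 0)
  as.vector(v * (n2 / ((1 + n2) * sqrt(n2 + eps))))
}

# Row-wise squash on a matrix of slot vectors. Hot path: no input checks.
squash_rows <- function(m, eps = 1e-8) {
  n2 <- rowSums(m * m)
  m * (n2 / ((1 + n2) * sqrt(n2 + eps)))
}

# Backward pass of squash_rows. m: pre-squash rows, g: gradient w.r.t the
# squashed rows. o = v * f(n2), f(n2) = n2 / ((1+n2) sqrt(n2+eps)), so
# dv = f*g + v * 2 f'(n2) * <v, g>.
squash_rows_backward <- function(m, g, eps = 1e-8) {
  n2 <- rowSums(m * m)
  s <- sqrt(n2 + eps)
  f <- n2 / ((1 + n2) * s)
  fp <- 1 / ((1 + n2) * s) - n2 / ((1 + n2)^2 * s) - n2 / (2 * (1 + n2) * s^3)
  g * f + m * (2 * fp * rowSums(m * g))
}

#' MaxMin normalization
#'
#' Affinely rescales values so that, along each slice of \code{axis}, the
#' minimum maps to \code{lb} and the maximum to \code{ub}. Used both to
#' renormalize masked image regions and to map binding-coefficient scores
#' into a common range. A degenerate slice (max equal to min) maps to
#' all-\code{ub}: when scores do not discriminate, nothing is suppressed.
#'
#' @param x Numeric vector or matrix, finite.
#' @param lb,ub Target bounds, \code{lb < ub}.
#' @param axis For matrices: 1 normalizes within each row, 2 within each
#'   column, NULL (default) over the whole object.
#' @return Same shape as \code{x}, values in \code{[lb, ub]}.
#' @examples
#' maxmin_normalize(c(1, 2, 3))          # 0, 0.5, 1
#' maxmin_normalize(c(2, 4), 0.5, 1)     # 0.5, 1
#' @export
maxmin_normalize <- function(x, lb = 0, ub = 1, axis = NULL) {
  if (!all(is.finite(x))) stop("maxmin_normalize: input must be finite")
  if (lb >= ub) stop("maxmin_normalize: lb must be < ub")
  if (is.matrix(x) && !is.null(axis)) {
    if (axis == 1) {
      mn <- apply(x, 1, min); mx <- apply(x, 1, max)
      rng <- mx - mn
      out <- lb + (ub - lb) * (x - mn) / ifelse(rng > 0, rng, 1)
      out[rng == 0, ] <- ub
      return(out)
    } else if (axis == 2) {
      return(t(maxmin_normalize(t(x), lb, ub, axis = 1)))
    } else stop("maxmin_normalize: axis must be 1, 2 or NULL")
  }
  mn <- min(x); mx <- max(x)
  if (mx == mn) {
    out <- x; out[] <- ub
    return(out)
  }
  lb + (ub - lb) * (x - mn) / (mx - mn)
}

#' Classification confidence from class likelihoods
#'
#' Normalizes a nonnegative class-likelihood vector to a probability
#' distribution and computes its Shannon entropy in nats. The model is
#' "confident" when the entropy falls below \code{threshold}; the default
#' 0.6 nats is the stopping criterion of the inference loop. With N classes
#' the entropy ceiling is \code{log(N)} (2.3026 nats for 10 classes), reached
#' by uniform likelihoods. An all-zero score vector is treated as maximally
#' uncertain (uniform), not an error.
#'
#' Slot-norm likelihoods live in \[0, 1), so they are treated as an
#' unnormalized distribution and divided by their sum; a Boltzmann softmax
#' over such bounded scores could never reach a 0.6-nat threshold for 10
#' classes (see the methods vignette).
#'
#' @param class_scores Nonnegative numeric vector of per-class likelihoods.
#' @param threshold Entropy threshold in nats.
#' @return A list of class \code{ora_confidence} with elements
#'   \code{probabilities} (simplex vector), \code{entropy} (nats) and
#'   \code{confident} (logical).
#' @examples
#' confidence(rep(1, 10))$entropy        # log(10), not confident
#' confidence(c(0.9, 0.1))               # 0.325 nats, confident
#' @export
confidence <- function(class_scores, threshold = 0.6) {
  if (!all(is.finite(class_scores)) || any(class_scores < 0))
    stop("confidence: class scores must be finite and nonnegative")
  s <- sum(class_scores)
  p <- if (s > 0) class_scores / s else rep(1 / length(class_scores), length(class_scores))
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  structure(list(probabilities = p, entropy = h, confident = h < threshold),
            class = "ora_confidence")
}
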