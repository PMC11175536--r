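# Minimal neural-network primitives in base R. Activations are stored as
# 4-D arrays (N, H, W, C) and dense activations as (N, features) matrices;
# convolution is computed as a sum of 9 shifted BLAS matmuls (one per kernel
# tap) which avoids materialising an im2col buffer. Every forward returns
# the quantities its backward needs; backwards are analytic and checked
# against finite differences in the test suite.

# ---- random init -----------------------------------------------------------

# He-normal fan-in init for conv (kh, kw, cin, cout) and dense (din, dout).
init_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

init_dense <- function(din, dout, sd = sqrt(2 / din)) {
  matrix(stats::rnorm(din * dout, sd = sd), din, dout)
}

# ---- convolution (3x3 taps, stride 1, optional zero pad) -------------------

pad_nhwc <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

conv2d_forward <- function(x, w, b, pad = 0) {
  xp <- pad_nhwc(x, pad)
  d <- dim(xp); n <- d[1]; h <- d[2]; wd <- d[3]; cin <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  oh <- h - kh + 1; ow <- wd - kw + 1
  out <- matrix(rep(b, each = n * oh * ow), n * oh * ow, cout)
  for (ky in seq_len(kh)) {
    for (kx in seq_len(kw)) {
      sub <- xp[, ky:(ky + oh - 1), kx:(kx + ow - 1), , drop = FALSE]
      dim(sub) <- c(n * oh * ow, cin)
      wk <- w[ky, kx, , ]
      dim(wk) <- c(cin, cout)
      out <- out + sub %*% wk
    }
  }
  dim(out) <- c(n, oh, ow, cout)
  list(out = out, xp = xp, pad = pad)
}

conv2d_backward <- function(cache, w, dout) {
  xp <- cache$xp; pad <- cache$pad
  d <- dim(xp); n <- d[1]; cin <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  od <- dim(dout); oh <- od[2]; ow <- od[3]
  dm <- dout
  dim(dm) <- c(n * oh * ow, cout)
  dw <- array(0, dim(w))
  dxp <- array(0, dim(xp))
  for (ky in seq_len(kh)) {
    for (kx in seq_len(kw)) {
      sub <- xp[, ky:(ky + oh - 1), kx:(kx + ow - 1), , drop = FALSE]
      dim(sub) <- c(n * oh * ow, cin)
      dw[ky, kx, , ] <- crossprod(sub, dm)
      wk <- w[ky, kx, , ]
      dim(wk) <- c(cin, cout)
      dsub <- tcrossprod(dm, wk)
      dim(dsub) <- c(n, oh, ow, cin)
      dxp[, ky:(ky + oh - 1), kx:(kx + ow - 1), ] <-
        dxp[, ky:(ky + oh - 1), kx:(kx + ow - 1), , drop = FALSE] + dsub
    }
  }
  db <- colSums(dm)
  if (pad > 0) {
    dx <- dxp[, (pad + 1):(d[2] - pad), (pad + 1):(d[3] - pad), , drop = FALSE]
  } else dx <- dxp
  list(dx = dx, dw = dw, db = db)
}

# ---- 2x2 max pooling, stride 2 --------------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x)
  ys <- seq(1, d[2], by = 2); xs <- seq(1, d[3], by = 2)
  a <- list(
    x[, ys, xs, , drop = FALSE], x[, ys + 1, xs, , drop = FALSE],
    x[, ys, xs + 1, , drop = FALSE], x[, ys + 1, xs + 1, , drop = FALSE]
  )
  best <- a[[1]]
  sel <- array(1L, dim(best))
  for (l in 2:4) {
    upd <- a[[l]] > best
    best[upd] <- a[[l]][upd]
    sel[upd] <- l
  }
  list(out = best, sel = sel, in_dim = d)
}

maxpool2_backward <- function(cache, dout) {
  d <- cache$in_dim
  ys <- seq(1, d[2], by = 2); xs <- seq(1, d[3], by = 2)
  dx <- array(0, d)
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (l in 1:4) {
    g <- dout * (cache$sel == l)
    dx[, ys + offs[[l]][1], xs + offs[[l]][2], ] <-
      dx[, ys + offs[[l]][1], xs + offs[[l]][2], , drop = FALSE] + g
  }
  dx
}

# ---- elementwise and dense -------------------------------------------------

relu_forward <- function(x) list(out = x * (x > 0), mask = x > 0)
relu_backward <- function(cache, dout) dout * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

dense_forward <- function(x, w, b) {
  list(out = sweep(x %*% w, 2, b, "+"), x = x)
}
dense_backward <- function(cache, w, dout) {
  list(dx = tcrossprod(dout, w), dw = crossprod(cache$x, dout), db = colSums(dout))
}

# Inverted dropout; mask is drawn from the active RNG stream.
dropout_forward <- function(x, p, train = TRUE) {
  if (!train || p <= 0) return(list(out = x, mask = NULL, p = p))
  mask <- (array(stats::runif(length(x)), dim(x) %||% length(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask, p = p)
}
dropout_backward <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
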