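# Independent brute-force trace of one binding iteration, written with
# scalar loops, used as the oracle for run_feature_binding().
brute_binding <- function(model, features, image, n_iter) {
  p <- model$params; cfg <- model$config
  nf <- cfg$n_feature_slots; df <- cfg$d_feature
  no <- cfg$n_classes; do_ <- cfg$d_object
  # votes f^_{j|i} = W_ij f_i from the row/column blocks of the vote tensor
  votes <- array(0, c(nf, no, do_))
  for (i in seq_len(nf)) for (j in seq_len(no)) {
    wij <- p$vote_w[((i - 1) * df + 1):(i * df),
                    ((j - 1) * do_ + 1):(j * do_)]
    votes[i, j, ] <- as.vector(features[i, ] %*% wij)
  }
  dec <- function(oflat) {   # naive decoder forward
    h1 <- pmax(0, as.vector(oflat %*% p$dec1_w) + p$dec1_b)
    h2 <- pmax(0, as.vector(h1 %*% p$dec2_w) + p$dec2_b)
    1 / (1 + exp(-(as.vector(h2 %*% p$dec3_w) + p$dec3_b)))
  }
  mm <- function(v) {        # maxmin to [0,1], degenerate -> all 1
    if (max(v) == min(v)) rep(1, length(v))
    else (v - min(v)) / (max(v) - min(v))
  }
  cm <- matrix(1, nf, no); bm <- matrix(0, nf, no); rm_ <- matrix(0, nf, no)
  for (t in seq_len(n_iter)) {
    o <- matrix(0, no, do_)
    for (j in seq_len(no)) {
      acc <- rep(0, do_)
      for (i in seq_len(nf)) acc <- acc + cm[i, j] * votes[i, j, ]
      o[j, ] <- squash(acc)
    }
    for (i in seq_len(nf)) for (j in seq_len(no))
      bm[i, j] <- bm[i, j] + sum(votes[i, j, ] * o[j, ])
    for (i in seq_len(nf)) bm[i, ] <- pmax(mm(bm[i, ]), 0.5)
    r <- numeric(no)
    for (j in seq_len(no)) {
      oflat <- rep(0, no * do_)
      oflat[((j - 1) * do_ + 1):(j * do_)] <- o[j, ]
      r[j] <- -mean((as.vector(image) - dec(oflat))^2)
    }
    rmap <- pmax(mm(r), 0.5)
    for (i in seq_len(nf)) rm_[i, ] <- rmap
    cm <- bm * rm_
  }
  o <- matrix(0, no, do_)
  for (j in seq_len(no)) {
    acc <- rep(0, do_)
    for (i in seq_len(nf)) acc <- acc + cm[i, j] * votes[i, j, ]
    o[j, ] <- squash(acc)
  }
  list(c = cm, b = bm, r = rm_, objects = o)
}
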