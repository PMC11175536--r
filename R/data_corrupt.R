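# Programmatic image corruption suite emulating the corruption families of
# the corrupted-handwritten-digit benchmarks (noise, fog, occlusion bands,
# zigzag and dotted-line strokes, spatter, blur, affine distortion). The
# benchmark itself ships single-severity corruptions; the five severity
# levels here are a documented extension so property tests can scale the
# perturbation strength. All operators are seed-deterministic,
# shape-preserving, clipped to [0, 1], and never touch labels.

corruption_kinds <- function() {
  c("identity", "gaussian_noise", "impulse_noise", "fog", "stripe",
    "zigzag", "dotted_line", "spatter", "blur", "affine")
}

# Severity parameter tables (index = severity 1..5).
corruption_levels <- list(
  gaussian_sigma   = c(0.05, 0.1, 0.2, 0.3, 0.4),
  impulse_fraction = c(0.01, 0.03, 0.06, 0.10, 0.15),
  fog_amplitude    = c(0.25, 0.40, 0.55, 0.70, 0.85),
  stripe_rows      = c(1, 2, 3, 4, 5),
  zigzag_strokes   = c(1, 1, 2, 2, 3),
  dotted_lines     = c(1, 1, 2, 2, 3),
  spatter_blobs    = c(2, 4, 6, 9, 12),
  blur_sigma       = c(0.5, 0.8, 1.2, 1.8, 2.5),
  affine_rotation  = c(4, 8, 12, 16, 20),       # degrees
  affine_scale     = c(0.04, 0.08, 0.12, 0.16, 0.20),
  affine_shear     = c(0.04, 0.08, 0.12, 0.16, 0.20),
  affine_shift     = c(1.0, 1.5, 2.0, 2.5, 3.0) # pixels
)

#' Corruption specification
#'
#' @param kind One of `"identity"`, `"gaussian_noise"`, `"impulse_noise"`,
#'   `"fog"`, `"stripe"`, `"zigzag"`, `"dotted_line"`, `"spatter"`,
#'   `"blur"`, `"affine"`.
#' @param severity Integer 1..5.
#' @param seed Integer seed; the same spec applied to the same image is
#'   bit-identical.
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(kind = "gaussian_noise", severity = 3, seed = 0) {
  kind <- match.arg(kind, corruption_kinds())
  stopifnot(severity >= 1, severity <= 5)
  structure(list(kind = kind, severity = as.integer(severity),
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Apply a corruption operator to an image
#'
#' @param image Square image matrix in `[0, 1]`.
#' @param spec A [corruption_spec()].
#' @return Corrupted image matrix, same shape, clipped to `[0, 1]`.
#' @export
corrupt <- function(image, spec) {
  stopifnot(inherits(spec, "corruption_spec"))
  if (spec$kind == "identity") return(image)
  lv <- corruption_levels
  sv <- spec$severity
  n <- nrow(image)
  with_seed(spec$seed, switch(spec$kind,
    gaussian_noise = clip01(image + matrix(stats::rnorm(n * n,
      sd = lv$gaussian_sigma[sv]), n, n)),
    impulse_noise = {
      out <- image
      k <- round(lv$impulse_fraction[sv] * n * n)
      idx <- sample(n * n, k)
      out[idx] <- stats::rbinom(k, 1, 0.5)
      out
    },
    fog = {
      noise <- matrix(stats::runif(n * n), n, n)
      haze <- filter_spatial_frequency(noise, "low", cutoff = 3)
      clip01(image + lv$fog_amplitude[sv] * haze)
    },
    stripe = {
      out <- image
      h <- lv$stripe_rows[sv]
      start <- sample(seq_len(n - h + 1), 1)
      if (stats::runif(1) < 0.5) out[start:(start + h - 1), ] <- 1
      else out[, start:(start + h - 1)] <- 1
      out
    },
    zigzag = {
      k <- lv$zigzag_strokes[sv]
      pls <- lapply(seq_len(k), function(i) {
        nseg <- 6
        xs <- seq(1, n, length.out = nseg + 1)
        y0 <- stats::runif(1, 0.2 * n, 0.8 * n)
        amp <- 0.12 * n
        ys <- y0 + amp * rep_len(c(-1, 1), nseg + 1) +
          stats::rnorm(nseg + 1, sd = 0.5)
        cbind(xs, ys)
      })
      pmax(image, render_strokes(pls, n, width = 0.9))
    },
    dotted_line = {
      k <- lv$dotted_lines[sv]
      out <- image
      px <- rep(seq_len(n), times = n); py <- rep(seq_len(n), each = n)
      for (i in seq_len(k)) {
        th <- stats::runif(1, 0, pi)
        cx <- stats::runif(1, 0.3 * n, 0.7 * n)
        cy <- stats::runif(1, 0.3 * n, 0.7 * n)
        tt <- seq(-n, n, by = 3)
        dots <- cbind(cx + tt * cos(th), cy + tt * sin(th))
        dots <- dots[dots[, 1] >= 1 & dots[, 1] <= n &
                     dots[, 2] >= 1 & dots[, 2] <= n, , drop = FALSE]
        add <- rep(0, n * n)
        for (d in seq_len(nrow(dots))) {
          d2 <- (py - dots[d, 1])^2 + (px - dots[d, 2])^2
          add <- pmax(add, pmin(1, pmax(0, 1.3 - sqrt(d2))))
        }
        out <- pmax(out, matrix(add, n, n))
      }
      out
    },
    spatter = {
      k <- lv$spatter_blobs[sv]
      px <- rep(seq_len(n), times = n); py <- rep(seq_len(n), each = n)
      add <- rep(0, n * n)
      for (i in seq_len(k)) {
        cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
        r <- stats::runif(1, 0.8, 2.0)
        a <- stats::runif(1, 0.5, 0.9)
        d2 <- (py - cx)^2 + (px - cy)^2
        add <- pmax(add, a * exp(-d2 / (2 * r^2)))
      }
      pmax(image, matrix(add, n, n))
    },
    blur = gaussian_blur(image, lv$blur_sigma[sv]),
    affine = {
      ang <- stats::runif(1, -1, 1) * lv$affine_rotation[sv] * pi / 180
      sc <- 1 + stats::runif(1, -1, 1) * lv$affine_scale[sv]
      sh <- stats::runif(1, -1, 1) * lv$affine_shear[sv]
      tr <- stats::runif(2, -1, 1) * lv$affine_shift[sv]
      affine_warp(image, ang, sc, sh, tr)
    }
  ))
}

# Separable Gaussian blur with reflected edges.
gaussian_blur <- function(image, sigma) {
  r <- max(1, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(image)
  idx <- function(i) pmin(n, pmax(1, i))          # clamp-pad
  conv1 <- function(m) {
    out <- m * 0
    for (o in -r:r) out <- out + k[o + r + 1] * m[idx(seq_len(n) + o), ,
                                                  drop = FALSE]
    out
  }
  t(conv1(t(conv1(image))))
}

# Inverse-mapped affine warp (rotation, isotropic scale, shear, translation
# about the image centre) with bilinear interpolation, zero outside.
affine_warp <- function(image, angle, scale, shear, translate) {
  n <- nrow(image)
  ctr <- (n + 1) / 2
  a <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2) %*%
       matrix(c(1, 0, shear, 1), 2, 2) * scale
  ainv <- solve(a)
  rr <- rep(seq_len(n), times = n) - ctr          # y (row)
  cc <- rep(seq_len(n), each = n) - ctr           # x (col)
  src_x <- ainv[1, 1] * (cc - translate[2]) + ainv[1, 2] * (rr - translate[1]) + ctr
  src_y <- ainv[2, 1] * (cc - translate[2]) + ainv[2, 2] * (rr - translate[1]) + ctr
  x0 <- floor(src_x); y0 <- floor(src_y)
  fx <- src_x - x0; fy <- src_y - y0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= n
    v <- numeric(length(yy))
    v[ok] <- image[cbind(yy[ok], xx[ok])]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(y0, x0) + fx * (1 - fy) * val(y0, x0 + 1) +
         (1 - fx) * fy * val(y0 + 1, x0) + fx * fy * val(y0 + 1, x0 + 1)
  matrix(clip01(out), n, n)
}

#' Corrupt a batch of images
#'
#' Applies `corrupt()` to each image, deriving each image's seed as
#' `spec$seed + i - 1` so batches are reproducible yet images are corrupted
#' independently. Labels are never altered by corruption; pass them through
#' unchanged.
#'
#' @param images (N, S, S) array.
#' @param spec A [corruption_spec()].
#' @return An (N, S, S) array of corrupted images.
#' @export
corrupt_batch <- function(images, spec) {
  out <- images
  for (i in seq_len(dim(images)[1])) {
    si <- spec; si$seed <- spec$seed + i - 1L
    out[i, , ] <- corrupt(images[i, , ], si)
  }
  out
}
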