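# Synthetic glyph dataset: ten digit-like stroke classes rendered from
# fixed skeletons (polylines and arcs on the unit square) with per-sample
# control-point jitter, translation and intensity jitter, anti-aliased onto
# a grayscale grid. Deterministic given the seed; stands in for handwritten
# digits so the whole pipeline is testable without downloads.

#' Glyph dataset specification
#'
#' @param n_classes Number of classes (at most 10 stroke skeletons exist).
#' @param samples_per_class Samples rendered per class.
#' @param image_size Canvas side in pixels (default 28).
#' @param stroke_jitter Standard deviation, in pixels, of the Gaussian
#'   jitter applied to each stroke control point.
#' @param intensity_jitter Maximum fraction by which a sample's stroke
#'   intensity is dimmed (uniform).
#' @param seed Integer seed; identical specs yield bit-identical datasets.
#' @return A list of class `glyph_spec`.
#' @export
glyph_spec <- function(n_classes = 10, samples_per_class = 100,
                       image_size = 28, stroke_jitter = 0.8,
                       intensity_jitter = 0.3, seed = 0) {
  if (n_classes > 10) stop("only 10 glyph skeletons are available")
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 image_size = as.integer(image_size),
                 stroke_jitter = stroke_jitter,
                 intensity_jitter = intensity_jitter,
                 seed = as.integer(seed)),
            class = "glyph_spec")
}

# Arc as a polyline; angles in degrees, y axis pointing down, theta = 180
# is the leftmost point, 270 the top, 0/360 the rightmost, 90 the bottom.
glyph_arc <- function(cx, cy, rx, ry, from, to, n = 14) {
  th <- seq(from, to, length.out = n) * pi / 180
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

# Skeletons in unit coordinates (x right, y down); one list of polylines
# (k x 2 matrices) per class 0..9.
glyph_skeletons <- function() {
  seg <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  list(
    `0` = list(glyph_arc(.50, .50, .26, .38, 0, 360)),
    `1` = list(seg(.36, .24, .52, .10, .52, .90)),
    `2` = list(glyph_arc(.50, .32, .22, .22, 180, 375),
               seg(.705, .38, .30, .88, .74, .88)),
    `3` = list(glyph_arc(.46, .30, .22, .20, 205, 430),
               glyph_arc(.46, .70, .24, .22, 290, 515)),
    `4` = list(seg(.58, .10, .24, .58, .80, .58), seg(.62, .32, .62, .92)),
    `5` = list(seg(.72, .10, .32, .10, .295, .44),
               glyph_arc(.46, .66, .25, .24, 245, 500)),
    `6` = list(glyph_arc(.49, .66, .23, .24, 0, 360),
               glyph_arc(.78, .52, .52, .44, 190, 245)),
    `7` = list(seg(.26, .12, .76, .12, .42, .92)),
    `8` = list(glyph_arc(.50, .30, .19, .20, 0, 360),
               glyph_arc(.50, .70, .23, .22, 0, 360)),
    `9` = list(glyph_arc(.47, .34, .22, .24, 0, 360),
               seg(.69, .40, .60, .92))
  )
}

# Render polylines (pixel coordinates) onto a size x size canvas with
# anti-aliased strokes of half-width `width`.
render_strokes <- function(polylines, size, width = 1.2, aa = 0.9) {
  px <- rep(seq_len(size), times = size)   # row index (y)
  py <- rep(seq_len(size), each = size)    # col index (x)
  d2min <- rep(Inf, size * size)
  for (pl in polylines) {
    for (s in seq_len(nrow(pl) - 1)) {
      a <- pl[s, ]; b <- pl[s + 1, ]
      abx <- b[1] - a[1]; aby <- b[2] - a[2]
      len2 <- abx^2 + aby^2
      # px is the y (row) coordinate, py the x (column) coordinate
      vx <- py - a[1]; vy <- px - a[2]
      t <- if (len2 > 0) pmin(1, pmax(0, (vx * abx + vy * aby) / len2)) else 0
      dx <- vx - t * abx; dy <- vy - t * aby
      d2 <- dx * dx + dy * dy
      d2min <- pmin(d2min, d2)
    }
  }
  img <- pmin(1, pmax(0, (width - sqrt(d2min)) / aa + 0.5))
  matrix(img, size, size)
}

#' Generate a synthetic glyph dataset
#'
#' Renders `n_classes * samples_per_class` anti-aliased glyph images with
#' per-sample jitter. Pixel intensities follow the handwritten-digit
#' convention: 0 is background, 1 is stroke.
#'
#' @param spec A [glyph_spec()].
#' @return A list with `images` (an (N, S, S) array in `[0, 1]`) and
#'   `labels` (integer vector, values `0 .. n_classes - 1`).
#' @export
generate_glyphs <- function(spec = glyph_spec()) {
  stopifnot(inherits(spec, "glyph_spec"))
  sk <- glyph_skeletons()[seq_len(spec$n_classes)]
  size <- spec$image_size
  margin <- 0.12 * size
  scale <- size - 1 - 2 * margin
  n <- spec$n_classes * spec$samples_per_class
  with_seed(spec$seed, {
    images <- array(0, c(n, size, size))
    labels <- integer(n)
    i <- 0L
    for (cl in seq_len(spec$n_classes)) {
      for (s in seq_len(spec$samples_per_class)) {
        i <- i + 1L
        labels[i] <- cl - 1L
        shift <- stats::runif(2, -2, 2)   # positional variance of the corpus
        wj <- stats::runif(1, 0.85, 1.15)
        amp <- 1 - stats::runif(1, 0, spec$intensity_jitter)
        pls <- lapply(sk[[cl]], function(pl) {
          p <- 1 + margin + pl * scale
          p + matrix(stats::rnorm(length(p), sd = spec$stroke_jitter),
                     nrow(p), 2) +
            matrix(shift, nrow(p), 2, byrow = TRUE)
        })
        images[i, , ] <- amp * render_strokes(pls, size, width = 1.2 * wj)
      }
    }
    list(images = images, labels = labels)
  })
}

#' Split a glyph dataset into disjoint train and test parts
#'
#' Stratified by class; the index sets are disjoint by construction.
#'
#' @param data A list with `images` and `labels` as from [generate_glyphs()].
#' @param test_fraction Fraction per class held out for testing.
#' @param seed Seed for the shuffle.
#' @return A list with `train` and `test`, each holding `images`, `labels`,
#'   and the original `indices`.
#' @export
glyph_split <- function(data, test_fraction = 0.2, seed = 0) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    test_idx <- integer(0)
    for (cl in unique(data$labels)) {
      idx <- which(data$labels == cl)
      k <- max(1, round(length(idx) * test_fraction))
      test_idx <- c(test_idx, sample(idx, k))
    }
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_along(data$labels), test_idx)
    take <- function(ix) list(images = data$images[ix, , , drop = FALSE],
                              labels = data$labels[ix], indices = ix)
    list(train = take(train_idx), test = take(test_idx))
  })
}

#' Compose two glyphs into an overlapping-pair image
#'
#' Renders two glyph images shifted in opposite directions onto a larger
#' canvas, pixelwise-maximum composited, for the sequential multi-object
#' task.
#'
#' @param img_a,img_b Source glyph matrices (same size).
#' @param canvas Canvas side in pixels (default 36 for 28-pixel sources).
#' @param shift Maximum absolute shift in pixels applied to each glyph in
#'   opposite directions (default 4).
#' @param seed Seed for the shift draw.
#' @return A `canvas` x `canvas` matrix in `[0, 1]`.
#' @export
compose_glyph_pair <- function(img_a, img_b, canvas = 36, shift = 4, seed = 0) {
  s <- nrow(img_a)
  stopifnot(canvas >= s)
  with_seed(seed, {
    off <- (canvas - s) %/% 2
    dxy <- sample(1:shift, 2, replace = TRUE) * sample(c(-1, 1), 2, TRUE)
    place <- function(img, d) {
      out <- matrix(0, canvas, canvas)
      r0 <- off + d[1]; c0 <- off + d[2]
      rr <- pmax(1, 1 + r0):pmin(canvas, s + r0)
      cc <- pmax(1, 1 + c0):pmin(canvas, s + c0)
      out[rr, cc] <- img[rr - r0, cc - c0]
      out
    }
    pmax(place(img_a, dxy), place(img_b, -dxy))
  })
}
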