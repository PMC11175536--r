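# Readers for the two standard distribution formats of the handwritten-digit
# corpora: the big-endian IDX container (images magic 2051, labels magic
# 2049) and the .npy array container used by the corrupted-digit benchmark.
# A minimal .npy v1.0 reader/writer is implemented here because no installed
# R package handles the format.

#' Read an IDX file
#'
#' Validates the big-endian magic number (2051 for uint8 image tensors,
#' 2049 for uint8 label vectors) and returns the decoded content. Images
#' are rescaled from uint8 to `[0, 1]`.
#'
#' @param path Path to an IDX file.
#' @param expect `"images"`, `"labels"`, or `"any"`.
#' @return For images, an (N, H, W) array in `[0, 1]`; for labels, an
#'   integer vector.
#' @export
read_idx <- function(path, expect = c("any", "images", "labels")) {
  expect <- match.arg(expect)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (expect == "images" && magic != 2051L)
    stop(sprintf("expected IDX image magic 2051, got %d in %s", magic, path))
  if (expect == "labels" && magic != 2049L)
    stop(sprintf("expected IDX label magic 2049, got %d in %s", magic, path))
  if (!magic %in% c(2051L, 2049L))
    stop(sprintf("unrecognised IDX magic %d in %s", magic, path))
  ndim <- if (magic == 2051L) 3L else 1L
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  total <- prod(dims)
  raw_data <- readBin(con, "integer", total, size = 1, signed = FALSE)
  if (length(raw_data) != total)
    stop(sprintf("IDX file %s truncated: expected %d bytes, got %d",
                 path, total, length(raw_data)))
  if (magic == 2049L) return(as.integer(raw_data))
  # stored row-major: (n, rows, cols) with cols fastest
  arr <- array(raw_data / 255, dim = rev(dims))   # (cols, rows, n)
  aperm(arr, c(3, 2, 1))
}

#' Write an IDX file
#'
#' Inverse of [read_idx()]; used to build fixtures and export datasets.
#'
#' @param x (N, H, W) numeric array in `[0, 1]` (written as uint8) or an
#'   integer label vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_idx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.array(x) && length(dim(x)) == 3) {
    writeBin(2051L, con, size = 4, endian = "big")
    writeBin(as.integer(dim(x)), con, size = 4, endian = "big")
    bytes <- as.integer(round(aperm(x, c(3, 2, 1)) * 255))
    writeBin(as.raw(bytes), con)
  } else {
    writeBin(2049L, con, size = 4, endian = "big")
    writeBin(length(x), con, size = 4, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}

# ---- minimal .npy v1.0 -----------------------------------------------------

npy_dtypes <- list(
  "|u1" = list(size = 1, what = "integer", signed = FALSE),
  "|i1" = list(size = 1, what = "integer", signed = TRUE),
  "<i2" = list(size = 2, what = "integer", signed = TRUE),
  "<i4" = list(size = 4, what = "integer", signed = TRUE),
  "<f4" = list(size = 4, what = "double", signed = TRUE),
  "<f8" = list(size = 8, what = "double", signed = TRUE)
)

#' Read a .npy array file
#'
#' Minimal NumPy v1.0 format reader for C-ordered numeric arrays
#' (uint8/int8/int16/int32/float32/float64, little-endian). Returns an R
#' array with the original shape and index order.
#'
#' @param path Path to a .npy file.
#' @return Numeric array (or vector for 1-D arrays).
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    stop(sprintf("%s is not a .npy file", path))
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] == 1) readBin(con, "integer", 1, size = 2, endian = "little")
          else readBin(con, "integer", 1, size = 4, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  dt <- npy_dtypes[[descr]]
  if (is.null(dt))
    stop(sprintf("unsupported .npy dtype '%s' in %s", descr, path))
  n <- if (length(shape)) prod(shape) else 1L
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) != n)
    stop(sprintf(".npy file %s truncated", path))
  if (length(shape) <= 1) return(vals)
  if (fortran) array(vals, shape)
  else aperm(array(vals, rev(shape)), rev(seq_along(shape)))
}

#' Write a .npy array file
#'
#' Writes a numeric array as C-ordered float64 (or uint8 when
#' `dtype = "|u1"`), v1.0 header.
#'
#' @param x Numeric array or vector.
#' @param path Output path.
#' @param dtype `"<f8"` (default) or `"|u1"`.
#' @return Invisibly, `path`.
#' @export
write_npy <- function(x, path, dtype = "<f8") {
  dt <- npy_dtypes[[dtype]]
  if (is.null(dt) || !dtype %in% c("<f8", "|u1"))
    stop("dtype must be '<f8' or '|u1'")
  shape <- dim(x) %||% length(x)
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    dtype, paste0(paste(shape, collapse = ", "),
                                  if (length(shape) == 1) "," else ""))
  pad <- (64 - (10 + nchar(header) + 1) %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  vals <- if (length(shape) > 1) as.vector(aperm(x, rev(seq_along(shape))))
          else as.vector(x)
  if (dtype == "|u1") writeBin(as.raw(as.integer(round(vals))), con)
  else writeBin(as.double(vals), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a standard digit dataset
#'
#' Loads either an MNIST-style IDX pair or an MNIST-C-style .npy pair.
#' `path` may be a length-2 named vector `c(images = ..., labels = ...)` or
#' a directory, in which case conventional file names are tried
#' (`*images*idx*` / `*labels*idx*` for IDX; `test_images.npy` /
#' `test_labels.npy` or `train_images.npy` / `train_labels.npy` for .npy).
#'
#' @param path File pair or directory.
#' @param which `"mnist_idx"` or `"mnistc_npy"`.
#' @return A list with `images` ((N, H, W) array in `[0, 1]`) and `labels`
#'   (integer vector), checked for matching lengths.
#' @export
read_standard_dataset <- function(path, which = c("mnist_idx", "mnistc_npy")) {
  which <- match.arg(which)
  if (length(path) == 1 && dir.exists(path)) {
    if (which == "mnist_idx") {
      imgs <- list.files(path, pattern = "images.*idx|idx3", full.names = TRUE)
      labs <- list.files(path, pattern = "labels.*idx|idx1", full.names = TRUE)
    } else {
      imgs <- file.path(path, c("test_images.npy", "train_images.npy"))
      labs <- file.path(path, c("test_labels.npy", "train_labels.npy"))
      imgs <- imgs[file.exists(imgs)]; labs <- labs[file.exists(labs)]
    }
    if (!length(imgs) || !length(labs))
      stop(sprintf("no %s image/label pair found under %s", which, path))
    path <- c(images = imgs[1], labels = labs[1])
  }
  if (length(path) != 2)
    stop("path must be a directory or c(images = ..., labels = ...)")
  if (is.null(names(path))) names(path) <- c("images", "labels")
  if (which == "mnist_idx") {
    images <- read_idx(path[["images"]], expect = "images")
    labels <- read_idx(path[["labels"]], expect = "labels")
  } else {
    images <- read_npy(path[["images"]])
    if (max(images) > 1) images <- images / 255
    if (length(dim(images)) == 4 && dim(images)[4] == 1)
      images <- array(images, dim(images)[1:3])
    labels <- as.integer(read_npy(path[["labels"]]))
  }
  if (dim(images)[1] != length(labels))
    stop(sprintf("image count (%d) does not match label count (%d)",
                 dim(images)[1], length(labels)))
  list(images = images, labels = labels)
}

#' Export images as PNG files for inspection
#'
#' @param images (N, S, S) array in `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written file names.
#' @export
export_png <- function(images, dir, prefix = "img") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(images)[1]
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    grDevices::png(files[i], width = dim(images)[2], height = dim(images)[3])
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(images[i, dim(images)[2]:1, ]),
                    col = grDevices::gray.colors(256, 0, 1), axes = FALSE)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(files)
}
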