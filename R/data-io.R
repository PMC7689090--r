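#' Labeled dataset container
#'
#' @param X sample matrix, values in `[0, 1]`, one row per sample.
#' @param y integer labels in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @param name optional dataset name.
#' @return An object of class `snn_dataset`.
#' @export
snn_dataset <- function(X, y, n_classes, name = "dataset") {
  X <- as_act(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) {
    stop_dim("X has %d rows but y has %d labels", nrow(X), length(y))
  }
  if (nrow(X) > 0 && (min(X) < 0 || max(X) > 1)) {
    stop("X entries must lie in [0, 1]", call. = FALSE)
  }
  n_classes <- as.integer(n_classes)
  if (length(y) > 0 && (min(y) < 0L || max(y) >= n_classes)) {
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  }
  structure(list(X = X, y = y, n_classes = n_classes, name = name),
            class = "snn_dataset")
}

#' @export
print.snn_dataset <- function(x, ...) {
  cat(sprintf("<snn_dataset '%s'> %d samples x %d features, %d classes\n",
              x$name, nrow(x$X), ncol(x$X), x$n_classes))
  invisible(x)
}

IDX_MAGIC_IMAGES <- 2051L  # 0x00000803
IDX_MAGIC_LABELS <- 2049L  # 0x00000801

read_u32_be <- function(con) {
  v <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(v) != 1L) stop("truncated IDX header", call. = FALSE)
  v
}

#' Read an IDX image file
#'
#' Parses the big-endian IDX container used by MNIST-style datasets:
#' magic number `0x00000803`, three u32 dimensions (count, rows, cols) and
#' a uint8 pixel payload. Pixels are flattened row-major into `rows*cols`
#' vectors and scaled by 1/255 into `[0, 1]`.
#'
#' @param path file path.
#' @return Matrix of `n` rows by `rows*cols` columns, values in `[0, 1]`.
#' @export
read_idx_images <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_u32_be(con)
  if (magic != IDX_MAGIC_IMAGES) {
    stop(sprintf("bad IDX image magic: got %d, expected %d",
                 magic, IDX_MAGIC_IMAGES), call. = FALSE)
  }
  n <- read_u32_be(con)
  rows <- read_u32_be(con)
  cols <- read_u32_be(con)
  n_bytes <- n * rows * cols
  raw_px <- readBin(con, "raw", n = n_bytes)
  if (length(raw_px) != n_bytes) {
    stop(sprintf("truncated IDX image payload: expected %d bytes, got %d",
                 n_bytes, length(raw_px)), call. = FALSE)
  }
  if (n == 0L) return(matrix(numeric(0), nrow = 0L, ncol = rows * cols))
  # payload is sample-major; fill columns = samples then transpose
  m <- matrix(as.integer(raw_px), nrow = rows * cols, ncol = n)
  t(m) / 255
}

#' Read an IDX label file
#'
#' Magic number `0x00000801`, one u32 count, uint8 labels.
#'
#' @param path file path.
#' @return Integer label vector.
#' @export
read_idx_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_u32_be(con)
  if (magic != IDX_MAGIC_LABELS) {
    stop(sprintf("bad IDX label magic: got %d, expected %d",
                 magic, IDX_MAGIC_LABELS), call. = FALSE)
  }
  n <- read_u32_be(con)
  raw_y <- readBin(con, "raw", n = n)
  if (length(raw_y) != n) {
    stop(sprintf("truncated IDX label payload: expected %d bytes, got %d",
                 n, length(raw_y)), call. = FALSE)
  }
  as.integer(raw_y)
}

#' Write images to an IDX file
#'
#' Inverse of [read_idx_images()]: values in `[0, 1]` are scaled by 255 and
#' rounded to uint8. Used to emit synthetic datasets in the same container
#' real ones ship in, so downstream commands are format-agnostic.
#'
#' @param X sample matrix with `rows*cols` columns, values in `[0, 1]`.
#' @param path output path.
#' @param rows,cols image shape; defaults to a single row of all pixels.
#' @return `path`, invisibly.
#' @export
write_idx_images <- function(X, path, rows = 1L, cols = ncol(X)) {
  X <- as_act(X)
  if (rows * cols != ncol(X)) {
    stop_dim("rows*cols = %d does not match %d pixel columns",
             rows * cols, ncol(X))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(IDX_MAGIC_IMAGES, nrow(X), as.integer(rows), as.integer(cols)),
           con, size = 4L, endian = "big")
  px <- as.integer(round(t(X) * 255))
  writeBin(as.raw(px), con)
  invisible(path)
}

#' Write labels to an IDX file
#'
#' @param y integer labels in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_idx_labels <- function(y, path) {
  y <- as.integer(y)
  if (length(y) > 0 && (min(y) < 0L || max(y) > 255L)) {
    stop("IDX labels must fit in uint8", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(IDX_MAGIC_LABELS, length(y)), con, size = 4L, endian = "big")
  writeBin(as.raw(y), con)
  invisible(path)
}

#' One-hot target encoding
#'
#' @param y integer labels in `[0, n_classes)`.
#' @param n_classes number of classes (columns).
#' @param amplitude value placed at the label's column (default 1).
#' @return Matrix with `length(y)` rows; row `i` is `amplitude` at column
#'   `y[i] + 1` and zero elsewhere.
#' @export
one_hot <- function(y, n_classes, amplitude = 1.0) {
  y <- as.integer(y)
  n_classes <- as.integer(n_classes)
  if (length(y) > 0 && (min(y) < 0L || max(y) >= n_classes)) {
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  }
  m <- matrix(0, nrow = length(y), ncol = n_classes)
  m[cbind(seq_along(y), y + 1L)] <- amplitude
  m
}

#' Synthetic Gaussian-blob classification data
#'
#' Stand-in for MNIST-like data that preserves what the learner needs —
#' bounded inputs and class-conditional cluster structure — without images
#' or downloads. Class centers are drawn on a sphere of radius
#' `separation * noise_sd` around the cube center (redrawn until all
#' pairwise center distances reach that radius; clearly infeasible
#' geometries error out). Samples are center + isotropic Gaussian noise,
#' mapped into `[0, 1]` by a fixed shift-and-clip (`x + 0.5`, clipped).
#' Each class is split 2:1 into train and test.
#'
#' @param n_per_class samples per class (train + test together).
#' @param dim input dimension.
#' @param n_classes number of classes.
#' @param separation center spacing in units of `noise_sd`.
#' @param noise_sd within-class standard deviation.
#' @param seed integer seed; everything is deterministic given it.
#' @return List with `train` and `test`, both [snn_dataset()] objects.
#' @examples
#' d <- make_blobs(30, dim = 5, n_classes = 2, separation = 6,
#'                 noise_sd = 0.05, seed = 1)
#' d$train
#' @export
make_blobs <- function(n_per_class, dim, n_classes, separation, noise_sd,
                       seed) {
  stopifnot(n_per_class >= 1, dim >= 1, n_classes >= 1)
  if (separation <= 0 || noise_sd <= 0) {
    stop("separation and noise_sd must be positive", call. = FALSE)
  }
  radius <- separation * noise_sd
  if (radius > 0.45) {
    stop(sprintf(paste0("separation*noise_sd = %.3g is too large for the",
                        " unit cube after the [0,1] squash"), radius),
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  # centers on a sphere of the required radius; rejection-sample until all
  # pairwise gaps also reach it
  centers <- NULL
  for (attempt in seq_len(200L)) {
    dirs <- matrix(stats::rnorm(n_classes * dim), n_classes, dim)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cand <- dirs * radius
    if (n_classes == 1L || min(stats::dist(cand)) >= radius) {
      centers <- cand
      break
    }
  }
  if (is.null(centers)) {
    stop(sprintf(paste0("could not place %d class centers in %d dimensions",
                        " at separation %g; geometry infeasible"),
                 n_classes, dim, separation), call. = FALSE)
  }

  n_total <- n_per_class * n_classes
  X <- matrix(0, n_total, dim)
  y <- integer(n_total)
  for (k in seq_len(n_classes)) {
    idx <- ((k - 1L) * n_per_class + 1L):(k * n_per_class)
    noise <- matrix(stats::rnorm(n_per_class * dim, sd = noise_sd),
                    n_per_class, dim)
    X[idx, ] <- sweep(noise, 2L, centers[k, ], "+")
    y[idx] <- k - 1L
  }
  X <- pmin(pmax(X + 0.5, 0), 1)

  n_train_pc <- ceiling(2 * n_per_class / 3)
  train_idx <- unlist(lapply(seq_len(n_classes), function(k) {
    ((k - 1L) * n_per_class + 1L):((k - 1L) * n_per_class + n_train_pc)
  }))
  test_idx <- setdiff(seq_len(n_total), train_idx)
  list(
    train = snn_dataset(X[train_idx, , drop = FALSE], y[train_idx],
                        n_classes, "blobs-train"),
    test = snn_dataset(X[test_idx, , drop = FALSE], y[test_idx],
                       n_classes, "blobs-test")
  )
}
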