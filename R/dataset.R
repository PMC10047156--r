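#' Labeled dataset of feature vectors and integer class labels
#'
#' The input side of the information channel: one feature vector per sample
#' (values in \[-1, 1\]) and an integer class label in `0 .. n_classes - 1`.
#' Class labels follow the 0-based convention of digit-classification tasks.
#'
#' @param features Numeric matrix, samples in rows, features in columns.
#'   All values must lie in \[-1, 1\].
#' @param labels Integer vector of class labels, one per row of `features`,
#'   each in `0 .. n_classes - 1`.
#' @param n_classes Number of classes C (>= 2). Defaults to `max(labels) + 1`.
#' @return An object of class `labeled_dataset`: a list with elements
#'   `features`, `labels` and `n_classes`.
#' @export
labeled_dataset <- function(features, labels, n_classes = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("`features` must have one row per label")
  }
  if (anyNA(features) || anyNA(labels)) stop("missing values are not allowed")
  if (min(features) < -1 || max(features) > 1) {
    stop("feature values must lie in [-1, 1]")
  }
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("`n_classes` must be at least 2")
  if (any(labels < 0L) || any(labels >= n_classes)) {
    stop("labels must lie in 0 .. n_classes - 1")
  }
  structure(
    list(features = features, labels = labels, n_classes = n_classes),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d samples x %d features, %d classes\n",
    nrow(x$features), ncol(x$features), x$n_classes
  ))
  invisible(x)
}

#' Restrict a dataset to a one-versus-rest binary task
#'
#' Relabels samples of the target class as 1 and all others as 0, the coding
#' used when training single-output sub-networks.
#'
#' @param dataset A [labeled_dataset()].
#' @param class Target class (0-based).
#' @return A `labeled_dataset` with `n_classes = 2`.
#' @export
as_binary_dataset <- function(dataset, class) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  class <- as.integer(class)
  if (class < 0L || class >= dataset$n_classes) stop("invalid target class")
  labeled_dataset(dataset$features,
                  as.integer(dataset$labels == class),
                  n_classes = 2L)
}

#' Read and write datasets as CSV
#'
#' One sample per row; the label is the last column. Feature columns keep
#' their names on round trip.
#'
#' @param dataset A [labeled_dataset()].
#' @param path File path.
#' @param n_classes Optional class count override on read (defaults to
#'   `max(label) + 1`).
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a `labeled_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(dataset$features)
  df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, n_classes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab <- df[[ncol(df)]]
  labeled_dataset(as.matrix(df[-ncol(df)]), lab, n_classes = n_classes)
}

.read_idx_header <- function(con, expected_magic) {
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (!identical(magic, expected_magic)) {
    stop(sprintf("not an IDX file of the expected type (magic 0x%08x)", magic))
  }
  invisible(magic)
}

#' Read MNIST-style IDX image and label files
#'
#' `read_idx_images()` expects magic number `0x00000803` (unsigned byte
#' images, big-endian dimensions) and returns a samples x pixels matrix with
#' pixel values rescaled from 0..255 to \[-1, 1\]. `read_idx_labels()` expects
#' magic `0x00000801`. `read_idx_dataset()` combines both into a
#' [labeled_dataset()].
#'
#' @param path Path to an IDX file.
#' @param images_path,labels_path Paths to the image and label IDX files.
#' @param n_classes Class count for the combined dataset (default 10).
#' @return A numeric matrix, an integer vector, or a `labeled_dataset`.
#' @export
read_idx_images <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .read_idx_header(con, 2051L)
  dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
  n <- dims[1L]; npix <- dims[2L] * dims[3L]
  raw <- readBin(con, "integer", n = n * npix, size = 1L, signed = FALSE)
  if (length(raw) != n * npix) stop("truncated IDX image file")
  # pixels of one image are stored consecutively
  m <- matrix(as.double(raw), nrow = n, ncol = npix, byrow = TRUE)
  m / 255 * 2 - 1
}

#' @rdname read_idx_images
#' @export
read_idx_labels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .read_idx_header(con, 2049L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  lab <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(lab) != n) stop("truncated IDX label file")
  as.integer(lab)
}

#' @rdname read_idx_images
#' @export
read_idx_dataset <- function(images_path, labels_path, n_classes = 10L) {
  labeled_dataset(read_idx_images(images_path), read_idx_labels(labels_path),
                  n_classes = n_classes)
}
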