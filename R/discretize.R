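#' Fit a per-neuron binarizer on recorded hidden states
#'
#' Coarse-grains continuous hidden activations into binary symbols, one
#' independent one-dimensional fit per hidden neuron over all samples.
#'
#' With `method = "kmeans"` the two cluster centroids are fit with
#' [stats::kmeans()] (k = 2) from a deterministic initialization at the
#' neuron's minimum and maximum value; cluster 0 is always the lower-centroid
#' cluster. With `method = "median"` the threshold is the neuron's median,
#' which forces each bin to receive half the values (a maximum-entropy
#' coarse-graining); k-means instead follows the actual shape of the
#' activation distribution.
#'
#' A degenerate neuron whose values span (numerically) a single point cannot
#' be split into two clusters; all of its samples map to bit 0 and the neuron
#' is flagged in the `degenerate` field.
#'
#' @param states A `state_table` from [record_states()], or a plain numeric
#'   matrix of activations.
#' @param method `"kmeans"` (default) or `"median"`.
#' @return An object of class `binarizer`: list with `method`, `centers`
#'   (2 x neurons, ascending; `NA` for the median method), `thresholds`
#'   (median method), and logical `degenerate` per neuron.
#' @export
fit_binarizer <- function(states, method = c("kmeans", "median")) {
  method <- match.arg(method)
  act <- if (inherits(states, "state_table")) states$activations else as.matrix(states)
  if (nrow(act) < 2L) stop("at least 2 samples are required to fit a binarizer")
  nh <- ncol(act)
  centers <- matrix(NA_real_, 2L, nh)
  thresholds <- rep(NA_real_, nh)
  degenerate <- logical(nh)
  for (j in seq_len(nh)) {
    x <- act[, j]
    rng <- range(x)
    if (!is.finite(diff(rng)) || diff(rng) < 1e-12) {
      degenerate[j] <- TRUE
      centers[, j] <- rng[1L]
      thresholds[j] <- rng[1L]
      next
    }
    if (method == "kmeans") {
      km <- stats::kmeans(x, centers = matrix(rng, ncol = 1L), iter.max = 100L)
      centers[, j] <- sort(km$centers[, 1L])
    } else {
      thresholds[j] <- stats::median(x)
    }
  }
  if (any(degenerate)) {
    message(sprintf("binarizer: %d degenerate (constant) neuron(s) mapped to bit 0",
                    sum(degenerate)))
  }
  structure(
    list(method = method, n_neurons = nh, centers = centers,
         thresholds = thresholds, degenerate = degenerate),
    class = "binarizer"
  )
}

.assign_bits <- function(x, b, j) {
  if (b$degenerate[j]) return(integer(length(x)))
  if (b$method == "kmeans") {
    # nearer centroid wins; an exactly equidistant value goes to cluster 0
    as.integer((x - b$centers[1L, j]) > (b$centers[2L, j] - x))
  } else {
    as.integer(x > b$thresholds[j])
  }
}

#' Apply a binarizer to hidden states
#'
#' Maps each continuous activation to the nearer fitted centroid (ties to
#' cluster 0) or across the median threshold, and assembles the discrete
#' state table used by all entropy estimation: true label, predicted label,
#' and one bit per hidden neuron.
#'
#' @param states A `state_table` from [record_states()].
#' @param binarizer A fitted [fit_binarizer()] with matching neuron count.
#' @return A [discrete_state_table()].
#' @export
binarize <- function(states, binarizer) {
  stopifnot(inherits(states, "state_table"), inherits(binarizer, "binarizer"))
  act <- states$activations
  if (ncol(act) != binarizer$n_neurons) {
    stop("binarizer was fitted on a different number of neurons")
  }
  bits <- vapply(seq_len(ncol(act)),
                 function(j) .assign_bits(act[, j], binarizer, j),
                 integer(nrow(act)))
  bits <- matrix(bits, nrow = nrow(act))
  discrete_state_table(states$input_label, states$predicted_label, bits,
                       n_classes = states$n_classes)
}

#' Discrete state table
#'
#' Per-sample discrete symbols: the input class, the predicted class, and the
#' binarized hidden states. Per-class indicator variables (true label == i,
#' predicted label == i) are derived on demand by the information measures.
#' An optional `weight` vector (summing to 1) turns the table into an exact
#' joint distribution over its rows, as produced by [exact_relay_table()];
#' without weights every row counts 1/n.
#'
#' @param input_label Integer vector of true class labels (0-based).
#' @param predicted_label Integer vector of predicted labels, same length.
#' @param hidden_bits Binary (0/1) matrix, samples x hidden nodes.
#' @param n_classes Number of classes.
#' @param weight Optional non-negative row weights summing to 1.
#' @return An object of class `discrete_state_table`.
#' @export
discrete_state_table <- function(input_label, predicted_label, hidden_bits,
                                 n_classes, weight = NULL) {
  input_label <- as.integer(input_label)
  predicted_label <- as.integer(predicted_label)
  hidden_bits <- as.matrix(hidden_bits)
  storage.mode(hidden_bits) <- "integer"
  n <- length(input_label)
  if (length(predicted_label) != n || nrow(hidden_bits) != n) {
    stop("labels, predictions and hidden bits must be aligned by sample")
  }
  if (n < 1L) stop("the table must contain at least one sample")
  if (any(hidden_bits != 0L & hidden_bits != 1L)) {
    stop("hidden bits must be 0 or 1")
  }
  n_classes <- as.integer(n_classes)
  if (any(input_label < 0L) || any(input_label >= n_classes) ||
      any(predicted_label < 0L) || any(predicted_label >= n_classes)) {
    stop("labels must lie in 0 .. n_classes - 1")
  }
  if (!is.null(weight)) {
    weight <- as.double(weight)
    if (length(weight) != n || any(weight < 0) ||
        abs(sum(weight) - 1) > 1e-8) {
      stop("`weight` must be non-negative, one per row, and sum to 1")
    }
  }
  structure(
    list(input_label = input_label, predicted_label = predicted_label,
         hidden_bits = hidden_bits, n_classes = n_classes, weight = weight),
    class = "discrete_state_table"
  )
}

#' @export
print.discrete_state_table <- function(x, ...) {
  cat(sprintf("<discrete_state_table> %d %s, %d hidden bits, %d classes\n",
              length(x$input_label),
              if (is.null(x$weight)) "samples" else "weighted states",
              ncol(x$hidden_bits), x$n_classes))
  invisible(x)
}

#' Number of hidden nodes in a discrete state table
#' @param table A [discrete_state_table()].
#' @return Integer count of hidden-bit columns.
#' @export
n_hidden_nodes <- function(table) {
  stopifnot(inherits(table, "discrete_state_table"))
  ncol(table$hidden_bits)
}

#' Read and write discrete state tables as CSV
#'
#' One row per sample: `label`, `predicted`, then one `bit_<j>` column per
#' hidden node (and a `weight` column for exact-distribution tables).
#'
#' @param table A [discrete_state_table()].
#' @param path File path.
#' @param n_classes Optional class count override on read.
#' @return `write_discrete_csv()` returns `path` invisibly;
#'   `read_discrete_csv()` returns a `discrete_state_table`.
#' @export
write_discrete_csv <- function(table, path) {
  stopifnot(inherits(table, "discrete_state_table"))
  df <- data.frame(label = table$input_label, predicted = table$predicted_label)
  bits <- table$hidden_bits
  colnames(bits) <- paste0("bit_", seq_len(ncol(bits)))
  df <- cbind(df, bits)
  if (!is.null(table$weight)) df$weight <- table$weight
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_discrete_csv
#' @export
read_discrete_csv <- function(path, n_classes = NULL) {
  df <- utils::read.csv(path)
  bit_cols <- grep("^bit_", names(df))
  if (is.null(n_classes)) n_classes <- max(df$label, df$predicted) + 1L
  discrete_state_table(df$label, df$predicted, as.matrix(df[bit_cols]),
                       n_classes = n_classes, weight = df$weight)
}
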