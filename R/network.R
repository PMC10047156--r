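#' Feed-forward tanh network with argmax readout
#'
#' A minimal container for the networks analysed here: one hidden layer, tanh
#' activation on hidden and output units, and an argmax readout over the
#' output activations (ties broken toward the lowest index). Single-output
#' networks (one-versus-rest sub-networks) use a sign readout at threshold 0.
#'
#' @param weights List of two numeric matrices: input-to-hidden
#'   (features x hidden) and hidden-to-output (hidden x outputs).
#' @param biases List of two numeric vectors matching the hidden and output
#'   layer widths.
#' @return An object of class `relay_network`.
#' @export
relay_network <- function(weights, biases) {
  if (!is.list(weights) || !is.list(biases) ||
      length(weights) != 2L || length(biases) != 2L) {
    stop("`weights` and `biases` must each be lists of length 2 (one hidden layer)")
  }
  weights <- lapply(weights, function(w) {
    w <- as.matrix(w); storage.mode(w) <- "double"; w
  })
  biases <- lapply(biases, as.double)
  if (ncol(weights[[1L]]) != nrow(weights[[2L]])) {
    stop("layer shapes are not conformant: hidden widths disagree")
  }
  for (l in 1:2) {
    if (length(biases[[l]]) != ncol(weights[[l]])) {
      stop("bias length must equal the layer's output width")
    }
  }
  structure(list(weights = weights, biases = biases), class = "relay_network")
}

#' @export
print.relay_network <- function(x, ...) {
  s <- layer_sizes(x)
  cat(sprintf("<relay_network> %d-%d-%d (tanh/tanh, argmax readout)\n",
              s[1L], s[2L], s[3L]))
  invisible(x)
}

#' Layer sizes of a network
#'
#' @param net A [relay_network()].
#' @return Integer vector `c(inputs, hidden, outputs)`.
#' @export
layer_sizes <- function(net) {
  stopifnot(inherits(net, "relay_network"))
  c(nrow(net$weights[[1L]]), ncol(net$weights[[1L]]), ncol(net$weights[[2L]]))
}

.add_bias <- function(a, b) a + matrix(b, nrow(a), length(b), byrow = TRUE)

#' Forward pass through a network
#'
#' Computes hidden and output activations for a batch of inputs. `clamp`
#' forces the listed hidden activations to 0 after the hidden layer is
#' computed; because `tanh(0) = 0`, this is exactly equivalent to the
#' weight-zeroing lesion performed by [knockout()].
#'
#' @param net A [relay_network()].
#' @param x Numeric matrix of inputs (samples x features) or a single vector.
#' @param clamp Integer vector of hidden-node indices (1-based) whose
#'   activations are forced to 0.
#' @return List with numeric matrices `hidden` and `output`.
#' @export
forward_pass <- function(net, x, clamp = integer(0)) {
  stopifnot(inherits(net, "relay_network"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != nrow(net$weights[[1L]])) {
    stop("input width does not match the network's input layer")
  }
  h <- tanh(.add_bias(x %*% net$weights[[1L]], net$biases[[1L]]))
  if (length(clamp)) {
    .check_hidden_index(net, clamp)
    h[, clamp] <- 0
  }
  o <- tanh(.add_bias(h %*% net$weights[[2L]], net$biases[[2L]]))
  list(hidden = h, output = o)
}

.check_hidden_index <- function(net, nodes) {
  nodes <- as.integer(nodes)
  nh <- ncol(net$weights[[1L]])
  if (length(nodes) && (anyNA(nodes) || any(nodes < 1L) || any(nodes > nh))) {
    stop("hidden-node index out of range")
  }
  nodes
}

.readout <- function(output) {
  if (ncol(output) == 1L) {
    as.integer(output[, 1L] > 0)
  } else {
    max.col(output, ties.method = "first") - 1L
  }
}

#' Predicted class labels
#'
#' Argmax over output activations (0-based labels; ties go to the lowest
#' index). A single-output network predicts 1 when its activation exceeds 0.
#'
#' @inheritParams forward_pass
#' @return Integer vector of predicted labels.
#' @export
predict_labels <- function(net, x) .readout(forward_pass(net, x)$output)

#' Lesion hidden nodes of a network
#'
#' Returns a copy of the network in which each listed hidden node has its
#' incoming weights, bias, and outgoing weights set to 0.0, so its activation
#' is `tanh(0) = 0` for every input. The forward pass of the lesioned network
#' is bit-identical to clamping those activations to zero in the original.
#'
#' @param net A [relay_network()].
#' @param nodes Integer vector of hidden-node indices (1-based); may be empty.
#' @return A lesioned `relay_network`.
#' @export
knockout <- function(net, nodes) {
  stopifnot(inherits(net, "relay_network"))
  nodes <- .check_hidden_index(net, nodes)
  if (!length(nodes)) return(net)
  net$weights[[1L]][, nodes] <- 0
  net$biases[[1L]][nodes] <- 0
  net$weights[[2L]][nodes, ] <- 0
  net
}

#' Record hidden-layer states and predictions over a dataset
#'
#' Materializes the continuous precursor of the discrete hidden variable:
#' one row per sample with the true label, the predicted label, and the
#' hidden activations. Deterministic given the network and data.
#'
#' @param net A [relay_network()].
#' @param dataset A [labeled_dataset()].
#' @return An object of class `state_table`: list with `input_label`,
#'   `predicted_label`, `activations` (samples x hidden) and `n_classes`.
#' @export
record_states <- function(net, dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  fp <- forward_pass(net, dataset$features)
  structure(
    list(
      input_label = dataset$labels,
      predicted_label = .readout(fp$output),
      activations = fp$hidden,
      n_classes = dataset$n_classes
    ),
    class = "state_table"
  )
}

#' @export
print.state_table <- function(x, ...) {
  cat(sprintf("<state_table> %d samples, %d hidden nodes, %d classes\n",
              length(x$input_label), ncol(x$activations), x$n_classes))
  invisible(x)
}

#' Overall accuracy and per-class recall
#'
#' Recall of class i is the fraction of class-i samples predicted as i; a
#' class absent from the dataset gets recall `NA`.
#'
#' @param net A [relay_network()].
#' @param dataset A [labeled_dataset()].
#' @return List with `overall` and named numeric vector `recall`.
#' @export
evaluate_accuracy <- function(net, dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pred <- predict_labels(net, dataset$features)
  classes <- 0:(dataset$n_classes - 1L)
  recall <- vapply(classes, function(cl) {
    in_class <- dataset$labels == cl
    if (!any(in_class)) return(NA_real_)
    mean(pred[in_class] == cl)
  }, numeric(1))
  names(recall) <- classes
  list(overall = mean(pred == dataset$labels), recall = recall)
}
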