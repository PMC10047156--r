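#' @keywords internal
#' Plug-in joint entropy (bits) of a set of discrete columns.
#' `cols` is a matrix/data.frame (possibly with zero columns) aligned with
#' the weight vector `w` (non-negative, sums to 1). Zero columns mean "no
#' variable": entropy 0.
.entropy_bits <- function(cols, w) {
  if (is.null(dim(cols))) cols <- matrix(cols, ncol = 1L)
  if (ncol(cols) == 0L) return(0)
  key <- do.call(paste, c(lapply(seq_len(ncol(cols)), function(j) cols[, j]),
                          list(sep = "\r")))
  p <- rowsum(w, key, reorder = FALSE)[, 1L]
  p <- p[p > 0]
  -sum(p * log2(p))
}

.table_weights <- function(x, weights) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (is.null(weights)) return(rep(1 / n, n))
  weights <- as.double(weights)
  if (length(weights) != n) stop("`weights` must have one entry per sample")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be non-negative and sum to 1")
  }
  weights
}

.as_cols <- function(x) {
  if (is.null(x)) return(matrix(integer(0), nrow = 0L, ncol = 0L))
  if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
}

.mm_correction <- function(cols, n) {
  if (is.null(dim(cols))) cols <- matrix(cols, ncol = 1L)
  if (ncol(cols) == 0L) return(0)
  key <- do.call(paste, c(lapply(seq_len(ncol(cols)), function(j) cols[, j]),
                          list(sep = "\r")))
  (length(unique(key)) - 1) / (2 * n * log(2))
}

#' Plug-in joint entropy in bits
#'
#' Maximum-likelihood (plug-in) estimate of the joint Shannon entropy of the
#' tuple formed by the given columns, base-2, from empirical joint
#' frequencies. Only realized tuples enter the sum; the full product state
#' space is never enumerated. An optional Miller-Madow bias correction
#' (`(K - 1) / (2 n ln 2)` with K the number of observed states) is exposed
#' but off by default, matching the direct use of sampled entropies in the
#' method; it applies to equally-weighted samples only.
#'
#' @param x Vector, matrix or data frame of discrete columns (>= 1 column).
#' @param weights Optional per-sample probabilities summing to 1; without
#'   them each sample counts 1/n.
#' @param correction `"none"` (default) or `"miller-madow"`.
#' @return Entropy in bits.
#' @export
joint_entropy <- function(x, weights = NULL, correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  cols <- .as_cols(x)
  if (ncol(cols) == 0L) stop("at least one column is required")
  if (nrow(cols) == 0L) stop("at least one sample is required")
  w <- .table_weights(cols, weights)
  h <- .entropy_bits(cols, w)
  if (correction == "miller-madow") {
    if (!is.null(weights)) {
      stop("the Miller-Madow correction applies to equally-weighted samples only")
    }
    h <- h + .mm_correction(cols, nrow(cols))
  }
  h
}

#' Mutual information in bits
#'
#' `I(X;Y) = H(X) + H(Y) - H(X,Y)` from plug-in entropies; symmetric in its
#' arguments.
#'
#' @param x,y Vectors or matrices of discrete columns (aligned by sample).
#' @inheritParams joint_entropy
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, weights = NULL) {
  x <- .as_cols(x); y <- .as_cols(y)
  w <- .table_weights(x, weights)
  .entropy_bits(x, w) + .entropy_bits(y, w) - .entropy_bits(cbind(x, y), w)
}

#' Triplet co-information in bits
#'
#' The three-way inclusion-exclusion information
#' `I(X;Y;Z) = H(X) + H(Y) + H(Z) - H(X,Y) - H(X,Z) - H(Y,Z) + H(X,Y,Z)`,
#' invariant under any permutation of the three groups. Co-information can be
#' negative: for Z = X xor Y with independent fair bits it equals -1 bit.
#'
#' @param x,y,z Vectors or matrices of discrete columns (aligned by sample).
#' @inheritParams joint_entropy
#' @return Co-information in bits.
#' @export
co_information <- function(x, y, z, weights = NULL) {
  x <- .as_cols(x); y <- .as_cols(y); z <- .as_cols(z)
  w <- .table_weights(x, weights)
  .entropy_bits(x, w) + .entropy_bits(y, w) + .entropy_bits(z, w) -
    .entropy_bits(cbind(x, y), w) - .entropy_bits(cbind(x, z), w) -
    .entropy_bits(cbind(y, z), w) + .entropy_bits(cbind(x, y, z), w)
}

# input/output columns of a table: the full class variables, or the
# per-class indicators [label == class], [predicted == class]
.io_columns <- function(table, class = NULL) {
  if (is.null(class)) {
    list(x = table$input_label, y = table$predicted_label)
  } else {
    class <- as.integer(class)
    if (class < 0L || class >= table$n_classes) {
      stop("`class` must lie in 0 .. n_classes - 1")
    }
    list(x = as.integer(table$input_label == class),
         y = as.integer(table$predicted_label == class))
  }
}

#' Relay information of a hidden bipartition
#'
#' The relay information of a candidate relay set YR against its conditioning
#' set Y0 is the co-information between the input class, the output class and
#' YR, with every entropy term conditioned on Y0:
#' \deqn{I_R = I(X_{in}; X_{out}; Y_R \mid Y_0)}
#' computed as the seven-term inclusion-exclusion with each `H(.)` replaced
#' by `H(. , Y0) - H(Y0)`. Conditioning on Y0 shields the measure from inert
#' nodes that merely copy relay states: a Y0 that duplicates YR drives every
#' conditional term, and hence the whole measure, to zero. With `condition`
#' empty the measure reduces exactly to [co_information()] of the three
#' groups, and an empty `relay` set returns 0 by convention (no relay), which
#' keeps removal traces telescoping.
#'
#' With a `class`, the input side is the indicator `label == class` and the
#' output side the indicator `predicted == class` (particular relay
#' information for that class).
#'
#' @param table A [discrete_state_table()].
#' @param relay Integer vector of hidden-node indices forming YR (1-based).
#' @param condition Integer vector forming Y0; disjoint from `relay`.
#' @param class Optional class (0-based) for particular relay information;
#'   `NULL` uses the full class variables.
#' @return Relay information in bits.
#' @export
relay_information <- function(table, relay, condition = integer(0),
                              class = NULL) {
  stopifnot(inherits(table, "discrete_state_table"))
  relay <- as.integer(relay)
  condition <- as.integer(condition)
  nh <- ncol(table$hidden_bits)
  if (any(c(relay, condition) < 1L) || any(c(relay, condition) > nh)) {
    stop("hidden-node index out of range")
  }
  if (length(intersect(relay, condition))) {
    stop("`relay` and `condition` must be disjoint")
  }
  if (!length(relay)) return(0)
  io <- .io_columns(table, class)
  w <- .table_weights(table$input_label, table$weight)
  a <- matrix(io$x, ncol = 1L)
  b <- matrix(io$y, ncol = 1L)
  r <- table$hidden_bits[, relay, drop = FALSE]
  y0 <- table$hidden_bits[, condition, drop = FALSE]
  h0 <- .entropy_bits(y0, w)
  hc <- function(...) .entropy_bits(cbind(..., y0), w) - h0
  hc(a) + hc(b) + hc(r) - hc(a, b) - hc(a, r) - hc(b, r) + hc(a, b, r)
}

#' @rdname relay_information
#' @param ... Passed on to [relay_information()].
#' @export
particular_relay_information <- function(table, class, relay,
                                         condition = integer(0), ...) {
  relay_information(table, relay = relay, condition = condition,
                    class = class, ...)
}
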