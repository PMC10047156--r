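#' Sylvester Hadamard matrix
#'
#' Rows are mutually orthogonal +/-1 vectors; used as class prototypes so
#' that Bayes-optimal behaviour of the pattern task is computable in closed
#' form.
#'
#' @param n Matrix order; a power of 2.
#' @return An n x n matrix with entries +/-1.
#' @export
hadamard_matrix <- function(n) {
  if (n < 1 || bitwAnd(n, n - 1L) != 0L) stop("`n` must be a power of 2")
  h <- matrix(1, 1L, 1L)
  while (nrow(h) < n) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

#' Generate a separable pattern dataset
#'
#' A stand-in for image classification with controllable difficulty: class i
#' gets the i-th row of a Hadamard matrix as its +/-1 prototype (orthogonal
#' by construction), each sample is its class prototype plus bounded uniform
#' feature noise (clipped to \[-1, 1\]), and the recorded label is flipped to
#' a random other class with probability `noise`. With `noise = 0` the
#' classes are linearly separable, so the Bayes accuracy is 1 by
#' construction; label flips lower that floor to `1 - noise`.
#'
#' @param n_classes Number of classes C (>= 2).
#' @param n_features Number of features F; a power of 2 with `F >= C`.
#' @param n Number of samples.
#' @param noise Label-flip probability in \[0, 0.5).
#' @param feature_noise Half-width of the uniform feature noise (default 0.3).
#' @param seed Integer seed; the dataset is deterministic given the seed.
#' @return A [labeled_dataset()] with attributes `prototypes` (C x F matrix)
#'   and `seed`.
#' @export
generate_pattern_dataset <- function(n_classes, n_features, n, noise = 0.02,
                                     feature_noise = 0.3, seed = 1L) {
  n_classes <- as.integer(n_classes)
  n_features <- as.integer(n_features)
  if (n_classes < 2L) stop("`n_classes` must be at least 2")
  if (n_features < n_classes) stop("`n_features` must be at least `n_classes`")
  if (noise < 0 || noise >= 0.5) stop("`noise` must lie in [0, 0.5)")
  proto <- hadamard_matrix(n_features)[seq_len(n_classes), , drop = FALSE]
  set.seed(as.integer(seed))
  labels <- sample.int(n_classes, n, replace = TRUE) - 1L
  feats <- proto[labels + 1L, , drop = FALSE] +
    matrix(stats::runif(n * n_features, -feature_noise, feature_noise),
           n, n_features)
  feats <- pmin(pmax(feats, -1), 1)
  observed <- labels
  if (noise > 0) {
    flip <- stats::runif(n) < noise
    if (any(flip)) {
      shift <- sample.int(n_classes - 1L, sum(flip), replace = TRUE)
      observed[flip] <- (labels[flip] + shift) %% n_classes
    }
  }
  out <- labeled_dataset(feats, observed, n_classes = n_classes)
  attr(out, "prototypes") <- proto
  attr(out, "seed") <- as.integer(seed)
  out
}

# analytic one-versus-rest sub-network for class `class`: hidden node 1
# matches the first half of the class prototype, hidden node 2 the second
# half, and the output fires only when both halves agree (a conjunction), so
# both hidden nodes are needed to signal the class.
.planted_subnetwork <- function(prototypes, class, gain = 4) {
  f <- ncol(prototypes)
  half <- f / 2
  p <- prototypes[class + 1L, ]
  w1 <- cbind(
    c(p[seq_len(half)], numeric(half)) * gain / half,
    c(numeric(half), p[half + seq_len(half)]) * gain / half
  )
  w2 <- matrix(c(3, 3), 2L, 1L)
  net <- relay_network(list(w1, w2), list(numeric(2), -4))
  attr(net, "target_class") <- as.integer(class)
  net
}

#' Build a composite network with planted relay nodes
#'
#' Constructs, without any training, a composite network whose ground-truth
#' relay structure is known: for each class an analytic two-hidden-node
#' one-versus-rest detector (each node matches one half of the class
#' prototype; the output is a conjunction of the two halves) is assembled
#' via [compose_networks()], so class i's output depends only on hidden
#' slots `(2i+1, 2i+2)`. Optionally appends inert nodes (zero in- and
#' out-weights) and redundant copies of existing hidden nodes (duplicated
#' incoming weights, zero outgoing weights, so the copy carries the same
#' state but drives nothing).
#'
#' Requires `n_classes <= n_features / 2` so that prototype halves remain
#' mutually orthogonal and each detector is silent on other classes.
#'
#' @param n_classes Number of classes C.
#' @param n_features Number of features F; a power of 2 with `F >= 2 C`.
#' @param gain Steepness of the hidden detectors (default 4).
#' @param n_inert Number of inert hidden nodes appended after the relay
#'   slots (default 0).
#' @param redundancy Integer vector of hidden slots to copy (default none).
#' @return List with `network` (a [relay_network()]), `relay_map` (class ->
#'   hidden slot pair), `inert_nodes`, `redundant_nodes` (indices of the
#'   appended copies) and `prototypes`.
#' @export
make_planted_relay_network <- function(n_classes, n_features, gain = 4,
                                       n_inert = 0L, redundancy = integer(0)) {
  n_classes <- as.integer(n_classes)
  n_features <- as.integer(n_features)
  if (n_classes > n_features / 2) {
    stop("planted construction requires `n_classes <= n_features / 2`")
  }
  proto <- hadamard_matrix(n_features)[seq_len(n_classes), , drop = FALSE]
  subnets <- lapply(0:(n_classes - 1L), function(cl) {
    .planted_subnetwork(proto, cl, gain = gain)
  })
  net <- compose_networks(subnets)
  relay_map <- attr(net, "relay_map")
  w1 <- net$weights[[1L]]; b1 <- net$biases[[1L]]
  w2 <- net$weights[[2L]]
  n_inert <- as.integer(n_inert)
  inert_nodes <- integer(0)
  if (n_inert > 0L) {
    w1 <- cbind(w1, matrix(0, nrow(w1), n_inert))
    b1 <- c(b1, numeric(n_inert))
    w2 <- rbind(w2, matrix(0, n_inert, ncol(w2)))
    inert_nodes <- ncol(w1) - rev(seq_len(n_inert)) + 1L
  }
  redundancy <- as.integer(redundancy)
  redundant_nodes <- integer(0)
  if (length(redundancy)) {
    if (any(redundancy < 1L) || any(redundancy > 2L * n_classes)) {
      stop("`redundancy` must reference existing relay slots")
    }
    w1 <- cbind(w1, net$weights[[1L]][, redundancy, drop = FALSE])
    b1 <- c(b1, net$biases[[1L]][redundancy])
    w2 <- rbind(w2, matrix(0, length(redundancy), ncol(w2)))
    redundant_nodes <- ncol(w1) - rev(seq_len(length(redundancy))) + 1L
  }
  out_net <- relay_network(list(w1, w2), list(b1, net$biases[[2L]]))
  attr(out_net, "relay_map") <- relay_map
  list(network = out_net, relay_map = relay_map, inert_nodes = inert_nodes,
       redundant_nodes = redundant_nodes, prototypes = proto)
}

.detector_state_probs <- function(fire_prob, encoding) {
  # probabilities of the four pair states (b1, b2) in (00, 01, 10, 11) order
  if (encoding == "and") {
    c((1 - fire_prob) / 3, (1 - fire_prob) / 3, (1 - fire_prob) / 3, fire_prob)
  } else {  # xor: firing = odd parity
    c((1 - fire_prob) / 2, fire_prob / 2, fire_prob / 2, (1 - fire_prob) / 2)
  }
}

.detector_fired <- function(state, encoding) {
  if (encoding == "and") state == 3L else state %in% c(1L, 2L)
}

#' Analytically exact planted-relay state table
#'
#' Builds a [discrete_state_table()] whose row weights are the exact joint
#' probabilities of a planted relay model, computed by enumeration of the
#' generative process rather than by sampling, so information identities
#' (monotonicity across nested sets, greedy optimality, telescoping) hold
#' without sampling noise.
#'
#' The generative model: the input class is drawn from `class_probs`; each
#' detector class i owns a pair of hidden bits that fires with probability
#' `fidelity` when the class is i and `false_rate` otherwise. Under the
#' `"and"` encoding a firing pair is in state (1,1) and a silent pair is
#' uniform over the other three states, so each member is individually
#' informative and the pair is a conjunction. Under the `"xor"` encoding
#' firing means odd parity, each member alone is marginally independent of
#' the class (the information is encrypted in the pair). The predicted label
#' is the lowest-index firing detector class, or `fallback_class` when no
#' detector fires. Junk bits are independent fair coins, inert bits are
#' constant 0, and `redundancy` appends exact copies of existing bit
#' columns.
#'
#' @param n_classes Number of classes (>= 2).
#' @param detect_classes Classes owning a detector pair (default: class 1
#'   only, a one-versus-rest channel; use `0:(n_classes-1)` for a full
#'   composite analogue).
#' @param encoding `"and"` (default) or `"xor"`.
#' @param fidelity P(pair fires | its class); default 0.95.
#' @param false_rate P(pair fires | another class); default 0.05.
#' @param n_junk Independent fair-coin hidden bits (default 2).
#' @param n_inert Constant hidden bits (default 1).
#' @param redundancy Integer vector of bit columns to copy (default none).
#' @param class_probs Class distribution (default uniform).
#' @param fallback_class Predicted label when no detector fires (default the
#'   lowest class without a detector, or 0).
#' @return A weighted `discrete_state_table` with attributes `relay_map`
#'   (detector class -> bit columns), `junk_nodes`, `inert_nodes`,
#'   `redundant_nodes` and `spec` (the generating parameters).
#' @export
exact_relay_table <- function(n_classes = 2L, detect_classes = 1L,
                              encoding = c("and", "xor"),
                              fidelity = 0.95, false_rate = 0.05,
                              n_junk = 2L, n_inert = 1L,
                              redundancy = integer(0),
                              class_probs = NULL, fallback_class = NULL) {
  encoding <- match.arg(encoding)
  n_classes <- as.integer(n_classes)
  detect_classes <- sort(as.integer(detect_classes))
  if (n_classes < 2L) stop("`n_classes` must be at least 2")
  if (any(detect_classes < 0L) || any(detect_classes >= n_classes)) {
    stop("`detect_classes` must lie in 0 .. n_classes - 1")
  }
  if (fidelity <= 0 || fidelity > 1 || false_rate < 0 || false_rate >= 1) {
    stop("`fidelity` must lie in (0, 1] and `false_rate` in [0, 1)")
  }
  if (is.null(class_probs)) class_probs <- rep(1 / n_classes, n_classes)
  if (length(class_probs) != n_classes || any(class_probs <= 0) ||
      abs(sum(class_probs) - 1) > 1e-8) {
    stop("`class_probs` must be a positive distribution over the classes")
  }
  d <- length(detect_classes)
  n_junk <- as.integer(n_junk); n_inert <- as.integer(n_inert)
  n_states <- n_classes * 4^d * 2^n_junk
  if (n_states > 65536) {
    stop(sprintf("state space too large for exact enumeration (%d > 65536)",
                 n_states))
  }
  if (is.null(fallback_class)) {
    free <- setdiff(0:(n_classes - 1L), detect_classes)
    fallback_class <- if (length(free)) min(free) else 0L
  }

  grid <- expand.grid(c(
    list(label = 0:(n_classes - 1L)),
    stats::setNames(rep(list(0:3), d), paste0("det", seq_len(d))),
    stats::setNames(rep(list(0:1), n_junk),
                    if (n_junk) paste0("junk", seq_len(n_junk)) else NULL)
  ), KEEP.OUT.ATTRS = FALSE)

  weight <- class_probs[grid$label + 1L]
  for (j in seq_len(d)) {
    fire_prob <- ifelse(grid$label == detect_classes[j], fidelity, false_rate)
    st <- grid[[paste0("det", j)]]
    p_and <- ifelse(st == 3L, fire_prob, (1 - fire_prob) / 3)
    p_xor <- ifelse(st %in% c(1L, 2L), fire_prob / 2, (1 - fire_prob) / 2)
    weight <- weight * if (encoding == "and") p_and else p_xor
  }
  if (n_junk > 0L) weight <- weight * 0.5^n_junk

  predicted <- rep(as.integer(fallback_class), nrow(grid))
  for (j in rev(seq_len(d))) {  # lowest firing detector class wins
    fired <- .detector_fired(grid[[paste0("det", j)]], encoding)
    predicted[fired] <- detect_classes[j]
  }

  bits <- matrix(0L, nrow(grid), 2L * d + n_junk + n_inert)
  relay_map <- list()
  for (j in seq_len(d)) {
    st <- grid[[paste0("det", j)]]
    cols <- c(2L * j - 1L, 2L * j)
    bits[, cols[1L]] <- st %/% 2L
    bits[, cols[2L]] <- st %% 2L
    relay_map[[as.character(detect_classes[j])]] <- cols
  }
  junk_nodes <- if (n_junk) 2L * d + seq_len(n_junk) else integer(0)
  for (j in seq_len(n_junk)) {
    bits[, junk_nodes[j]] <- grid[[paste0("junk", j)]]
  }
  inert_nodes <- if (n_inert) 2L * d + n_junk + seq_len(n_inert) else integer(0)

  redundant_nodes <- integer(0)
  redundancy <- as.integer(redundancy)
  if (length(redundancy)) {
    if (any(redundancy < 1L) || any(redundancy > ncol(bits))) {
      stop("`redundancy` must reference existing bit columns")
    }
    bits <- cbind(bits, bits[, redundancy, drop = FALSE])
    redundant_nodes <- ncol(bits) - rev(seq_len(length(redundancy))) + 1L
  }

  keep <- weight > 0
  out <- discrete_state_table(grid$label[keep], predicted[keep],
                              bits[keep, , drop = FALSE],
                              n_classes = n_classes,
                              weight = weight[keep] / sum(weight[keep]))
  attr(out, "relay_map") <- relay_map
  attr(out, "junk_nodes") <- junk_nodes
  attr(out, "inert_nodes") <- inert_nodes
  attr(out, "redundant_nodes") <- redundant_nodes
  attr(out, "spec") <- list(
    n_classes = n_classes, detect_classes = detect_classes,
    encoding = encoding, fidelity = fidelity, false_rate = false_rate,
    n_junk = n_junk, n_inert = n_inert, redundancy = redundancy,
    class_probs = class_probs, fallback_class = fallback_class
  )
  out
}

#' Randomized exact planted-relay table
#'
#' Draws a planted one-versus-rest relay specification at random (channel
#' fidelity in 0.85..0.98, false-fire rate in 0.02..0.08, 1-3 junk bits, 0-1
#' inert bits, biased class frequency) and permutes the hidden columns so
#' the relay pair sits at a random position. Used to exercise ground-truth
#' recovery over many seeded conditions.
#'
#' @param seed Integer seed.
#' @param n_classes Number of classes (default 2: a one-versus-rest channel).
#' @param encoding `"and"` (default) or `"xor"`.
#' @return As [exact_relay_table()], with the permutation applied to the
#'   `relay_map`, `junk_nodes` and `inert_nodes` attributes.
#' @export
random_exact_relay_table <- function(seed, n_classes = 2L,
                                     encoding = c("and", "xor")) {
  encoding <- match.arg(encoding)
  set.seed(as.integer(seed))
  p1 <- stats::runif(1, 0.15, 0.5)
  probs <- if (n_classes == 2L) c(1 - p1, p1) else NULL
  tab <- exact_relay_table(
    n_classes = n_classes,
    detect_classes = if (n_classes == 2L) 1L else 0:(n_classes - 1L),
    encoding = encoding,
    fidelity = stats::runif(1, 0.85, 0.98),
    false_rate = stats::runif(1, 0.02, 0.08),
    n_junk = sample(1:3, 1L),
    n_inert = sample(0:1, 1L),
    class_probs = probs
  )
  perm <- sample.int(ncol(tab$hidden_bits))
  inv <- order(perm)
  out <- discrete_state_table(tab$input_label, tab$predicted_label,
                              tab$hidden_bits[, perm, drop = FALSE],
                              n_classes = tab$n_classes, weight = tab$weight)
  attr(out, "relay_map") <- lapply(attr(tab, "relay_map"),
                                   function(cols) sort(inv[cols]))
  attr(out, "junk_nodes") <- sort(inv[attr(tab, "junk_nodes")])
  attr(out, "inert_nodes") <- sort(inv[attr(tab, "inert_nodes")])
  attr(out, "spec") <- attr(tab, "spec")
  out
}
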