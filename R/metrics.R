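#' Per-node information loss along a removal trace
#'
#' The information lost when node n was removed at its step:
#' `delta_I(n) = I_R(YR before removal) - I_R(YR after removal)`. Over a
#' complete trace the deltas telescope exactly to the relay information of
#' the full hidden layer (the empty final set contributes 0 by convention).
#' Small negative deltas can arise from sampling noise in the plug-in
#' estimator; they are kept as-is and flagged with a warning.
#'
#' @param trace A `removal_trace` from [greedy_shrink()].
#' @return Data frame with columns `step`, `node`, `delta` (bits).
#' @export
delta_information <- function(trace) {
  .check_complete_trace(trace)
  out <- trace$steps[, c("step", "node", "delta")]
  if (any(out$delta < -1e-9)) {
    warning("negative information deltas (estimator noise) present; kept unclipped")
  }
  rownames(out) <- NULL
  out
}

.check_complete_trace <- function(trace) {
  if (!inherits(trace, "removal_trace")) stop("`trace` must be a removal_trace")
  if (nrow(trace$steps) != trace$n_nodes ||
      !setequal(trace$steps$node, seq_len(trace$n_nodes))) {
    stop("incomplete trace: every node must be removed exactly once")
  }
  invisible(trace)
}

#' Aggregated relay information per node
#'
#' The cumulative information loss up to and including each node's removal
#' step: node removed at step n gets `I_A(n) = sum_{i <= n} delta_I(i)`.
#' Late-removed members of an "encrypted" essential set, whose own removal
#' step shows little loss only because earlier removals already exhausted
#' the information, still accumulate a large I_A; the last removed node
#' always carries the full-layer relay information.
#'
#' @param trace A `removal_trace` from [greedy_shrink()].
#' @return Data frame with columns `step`, `node`, `delta`, `aggregated`.
#' @export
aggregated_relay_information <- function(trace) {
  .check_complete_trace(trace)
  out <- trace$steps[, c("step", "node", "delta")]
  out$aggregated <- cumsum(out$delta)
  rownames(out) <- NULL
  out
}

#' Essentiality of single hidden nodes
#'
#' The relay information lost when one node is moved from the full hidden
#' set into the conditioning set:
#' `ess(n) = I_R(Y | Y0 = {}) - I_R(Y - n | Y0 = {n})`,
#' i.e. the full-set information delta of that single removal. A node that
#' is inert, or whose own state is individually uninformative about the
#' input/output pair (for example one member of a parity-coded pair, or a
#' copy of such a member), has essentiality 0 even when it belongs to an
#' essential set; single-node essentiality therefore under-reports nodes
#' whose contribution is synergistic.
#'
#' @param table A [discrete_state_table()].
#' @param nodes Hidden-node indices (1-based); default all nodes.
#' @param class Optional class (0-based) for particular relay information.
#' @return Named numeric vector of essentiality values in bits.
#' @export
essentiality <- function(table, nodes = NULL, class = NULL) {
  stopifnot(inherits(table, "discrete_state_table"))
  nh <- n_hidden_nodes(table)
  if (is.null(nodes)) nodes <- seq_len(nh)
  nodes <- as.integer(nodes)
  if (any(nodes < 1L) || any(nodes > nh)) stop("hidden-node index out of range")
  all_nodes <- seq_len(nh)
  ir_full <- relay_information(table, all_nodes, integer(0), class)
  out <- vapply(nodes, function(n) {
    ir_full - relay_information(table, setdiff(all_nodes, n), n, class)
  }, numeric(1))
  names(out) <- nodes
  out
}

#' Per-class node attribution report
#'
#' Runs the greedy search once per class and assembles node x class matrices
#' of the three attribution measures: the removal-step information loss
#' `delta`, the aggregated relay information, the single-node essentiality,
#' plus each node's removal rank (1 = removed first). The aggregated and
#' essentiality matrices reproduce the grayscale panels used to visualize
#' planted relays.
#'
#' @param table A [discrete_state_table()].
#' @param classes Integer vector of classes (0-based); default all classes.
#' @return An object of class `attribution_report`: list with matrices
#'   `delta`, `aggregated`, `essentiality`, `rank` (nodes x classes) and the
#'   per-class `traces`.
#' @export
attribution_report <- function(table, classes = NULL) {
  stopifnot(inherits(table, "discrete_state_table"))
  if (is.null(classes)) classes <- 0:(table$n_classes - 1L)
  classes <- as.integer(classes)
  nh <- n_hidden_nodes(table)
  mk <- function() {
    matrix(NA_real_, nh, length(classes),
           dimnames = list(node = seq_len(nh), class = classes))
  }
  delta <- mk(); aggregated <- mk(); ess <- mk(); rank <- mk()
  traces <- vector("list", length(classes))
  names(traces) <- classes
  for (j in seq_along(classes)) {
    cl <- classes[j]
    tr <- greedy_shrink(table, class = cl)
    agg <- aggregated_relay_information(tr)
    delta[agg$node, j] <- agg$delta
    aggregated[agg$node, j] <- agg$aggregated
    rank[agg$node, j] <- agg$step
    ess[, j] <- essentiality(table, class = cl)
    traces[[j]] <- tr
  }
  structure(
    list(delta = delta, aggregated = aggregated, essentiality = ess,
         rank = rank, traces = traces, classes = classes),
    class = "attribution_report"
  )
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> %d nodes x %d classes\n",
              nrow(x$delta), length(x$classes)))
  cat("aggregated relay information (bits):\n")
  print(round(x$aggregated, 3))
  invisible(x)
}
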