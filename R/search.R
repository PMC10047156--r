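#' Shrinking subset aggregation: greedy search for informative node sets
#'
#' Starts with the full hidden layer as the relay set YR (Y0 empty). At each
#' step every candidate single-node removal is scored by the relay
#' information of the shrunken set, `I_R(YR - a | Y0 + a)`; the node whose
#' removal retains the most information is permanently moved into Y0 (ties
#' broken toward the lowest node index). The process repeats until YR is
#' empty, so a layer of N nodes costs exactly `N (N + 1) / 2` candidate
#' relay-information evaluations (210 at N = 20), turning the exponential
#' bipartition search into a quadratic one.
#'
#' @param table A [discrete_state_table()].
#' @param class Optional class (0-based) to score particular relay
#'   information; `NULL` scores the full class variables.
#' @return An object of class `removal_trace`: list with
#'   \describe{
#'     \item{steps}{data frame with one row per removal: `step`, `node`
#'       (the removed node), `size_before`, `ir_before` (I_R of YR before the
#'       removal), `ir_after` (I_R retained after it), `delta`
#'       (`ir_before - ir_after`, the information lost at this step).}
#'     \item{candidates}{list of named numeric vectors; entry k holds the
#'       candidate I_R of every single-node removal evaluated at step k.}
#'     \item{ir_full}{I_R of the complete hidden layer (Y0 empty).}
#'     \item{n_evaluations}{count of candidate relay-information evaluations.}
#'   }
#' @export
greedy_shrink <- function(table, class = NULL) {
  stopifnot(inherits(table, "discrete_state_table"))
  n <- n_hidden_nodes(table)
  if (n < 1L) stop("the hidden layer is empty")
  yr <- seq_len(n)
  y0 <- integer(0)
  ir_full <- relay_information(table, yr, integer(0), class)
  ir_before <- ir_full
  n_eval <- 0L
  steps <- vector("list", n)
  candidates <- vector("list", n)
  for (k in seq_len(n)) {
    cand <- vapply(yr, function(a) {
      relay_information(table, setdiff(yr, a), c(y0, a), class)
    }, numeric(1))
    names(cand) <- yr
    n_eval <- n_eval + length(yr)
    best <- which.max(cand)  # first maximum = lowest node index (yr ascending)
    node <- yr[best]
    ir_after <- cand[[best]]
    steps[[k]] <- data.frame(
      step = k, node = node, size_before = length(yr),
      ir_before = ir_before, ir_after = ir_after,
      delta = ir_before - ir_after
    )
    candidates[[k]] <- cand
    yr <- setdiff(yr, node)
    y0 <- c(y0, node)
    ir_before <- ir_after
  }
  structure(
    list(steps = do.call(rbind, steps), candidates = candidates,
         ir_full = ir_full, n_nodes = n, n_evaluations = n_eval,
         class = class),
    class = "removal_trace"
  )
}

#' @export
print.removal_trace <- function(x, ...) {
  cat(sprintf(
    "<removal_trace> %d nodes%s, I_R(full) = %.4f bits, %d evaluations\n",
    x$n_nodes,
    if (is.null(x$class)) "" else sprintf(" (class %d)", x$class),
    x$ir_full, x$n_evaluations
  ))
  cat("removal order:", paste(x$steps$node, collapse = " "), "\n")
  invisible(x)
}

# the ordered YR sets visited by a trace: size n (full) down to size 1,
# paired with their relay information given the complementary Y0
.trace_sets <- function(trace) {
  n <- trace$n_nodes
  all_nodes <- seq_len(n)
  removed <- trace$steps$node
  sets <- vector("list", n)
  irs <- numeric(n)
  sets[[1L]] <- all_nodes
  irs[1L] <- trace$ir_full
  for (k in seq_len(n - 1L)) {
    sets[[k + 1L]] <- setdiff(sets[[k]], removed[k])
    irs[k + 1L] <- trace$steps$ir_after[k]
  }
  list(sets = sets, ir = irs, size = n:1)
}

#' Exhaustive bipartition search
#'
#' Evaluates the relay information of every nonempty subset YR of the hidden
#' layer against its complement Y0 (all `2^N - 1` bipartitions) and reports
#' the per-size maxima. Intended as the exact oracle for small layers; the
#' cost is exponential, so layers above `max_nodes` are refused with a
#' pointer to [greedy_shrink()].
#'
#' @param table A [discrete_state_table()].
#' @param class Optional class (0-based); `NULL` scores the full variables.
#' @param max_nodes Hard cap on the layer size (default 20; a warning is
#'   issued above 16).
#' @return An object of class `search_result`: list with
#'   \describe{
#'     \item{profile}{data frame of every subset: `size`, `ir`, and `nodes`
#'       (a list column of index vectors).}
#'     \item{best}{data frame of per-size maxima (`size`, `ir`).}
#'     \item{best_sets}{list (by size) of all subsets attaining that size's
#'       maximum within `1e-9` bits; equally informative maximal sets are
#'       reported side by side, never collapsed.}
#'   }
#' @export
exhaustive_search <- function(table, class = NULL, max_nodes = 20L) {
  stopifnot(inherits(table, "discrete_state_table"))
  n <- n_hidden_nodes(table)
  if (n > max_nodes) {
    stop(sprintf(
      "exhaustive search over %d nodes (%.0f bipartitions) refused; use greedy_shrink()",
      n, 2^n - 1
    ))
  }
  if (n > 16L) {
    warning(sprintf("exhaustive search over %d nodes evaluates %.0f bipartitions",
                    n, 2^n - 1))
  }
  all_nodes <- seq_len(n)
  profiles <- vector("list", n)
  for (size in seq_len(n)) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    ir <- vapply(subsets, function(s) {
      relay_information(table, s, setdiff(all_nodes, s), class)
    }, numeric(1))
    profiles[[size]] <- list(size = size, subsets = subsets, ir = ir)
  }
  profile <- data.frame(
    size = unlist(lapply(profiles, function(p) rep(p$size, length(p$ir))))
  )
  profile$ir <- unlist(lapply(profiles, function(p) p$ir))
  profile$nodes <- do.call(c, lapply(profiles, function(p) p$subsets))
  best <- data.frame(
    size = seq_len(n),
    ir = vapply(profiles, function(p) max(p$ir), numeric(1))
  )
  best_sets <- lapply(profiles, function(p) {
    p$subsets[p$ir >= max(p$ir) - 1e-9]
  })
  structure(
    list(profile = profile, best = best, best_sets = best_sets,
         method = "exhaustive", class = class,
         ir_full = best$ir[n], n_nodes = n),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s over %d nodes%s\n", x$method, x$n_nodes,
              if (is.null(x$class)) "" else sprintf(" (class %d)", x$class)))
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Minimal informative node set
#'
#' The smallest relay set along a search trajectory whose relay information
#' is still at least `(1 - epsilon)` times the relay information of the full
#' hidden layer. The relative threshold operationalizes "carries all of the
#' information" up to a tolerated loss; `epsilon = 0` demands the full value
#' (to numerical tolerance `tol`) and `epsilon = 1` accepts any set, so the
#' smallest is returned.
#'
#' @param x A `removal_trace` from [greedy_shrink()] or a `search_result`
#'   from [exhaustive_search()].
#' @param epsilon Tolerated relative information loss in \[0, 1\]
#'   (default 0.05).
#' @param tol Absolute numerical slack in bits (default 1e-9).
#' @return Sorted integer vector of hidden-node indices, with attributes
#'   `ir` (its relay information) and `ir_full`.
#' @export
minimal_set <- function(x, epsilon = 0.05, tol = 1e-9) {
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must lie in [0, 1]")
  UseMethod("minimal_set")
}

#' @export
minimal_set.removal_trace <- function(x, epsilon = 0.05, tol = 1e-9) {
  tr <- .trace_sets(x)
  # the trajectory ends at the empty set, I_R = 0 by convention
  sets <- c(tr$sets, list(integer(0)))
  irs <- c(tr$ir, 0)
  threshold <- (1 - epsilon) * x$ir_full - tol
  ok <- which(irs >= threshold)
  pick <- ok[length(ok)]  # sets are ordered by decreasing size
  out <- sort(sets[[pick]])
  attr(out, "ir") <- irs[pick]
  attr(out, "ir_full") <- x$ir_full
  out
}

#' @export
minimal_set.search_result <- function(x, epsilon = 0.05, tol = 1e-9) {
  threshold <- (1 - epsilon) * x$ir_full - tol
  if (0 >= threshold) {
    out <- integer(0)
    attr(out, "ir") <- 0
    attr(out, "ir_full") <- x$ir_full
    return(out)
  }
  sizes <- x$best$size[x$best$ir >= threshold]
  size <- min(sizes)
  out <- sort(x$best_sets[[size]][[1L]])
  attr(out, "ir") <- x$best$ir[size]
  attr(out, "ir_full") <- x$ir_full
  out
}
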