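#' Knockout effect of a hidden-node set on one class
#'
#' Lesions the listed nodes (see [knockout()]) and measures the drop in
#' class-specific recall:
#' `K = recall_class(intact) - recall_class(lesioned)`, a dimensionless value
#' in \[-1, 1\]. The empty set has effect 0 by construction. An alternative
#' definition via the drop in overall accuracy is available through
#' `measure = "overall"`.
#'
#' @param net A [relay_network()].
#' @param dataset A [labeled_dataset()].
#' @param nodes Hidden-node indices to knock out (may be empty).
#' @param class Class (0-based) whose recall is scored.
#' @param measure `"recall"` (default) or `"overall"`.
#' @return Knockout effect K.
#' @export
knockout_effect <- function(net, dataset, nodes, class,
                            measure = c("recall", "overall")) {
  measure <- match.arg(measure)
  stopifnot(inherits(dataset, "labeled_dataset"))
  class <- as.integer(class)
  if (class < 0L || class >= dataset$n_classes) stop("invalid class")
  if (!any(dataset$labels == class)) {
    stop(sprintf("class %d is absent from the dataset", class))
  }
  intact <- evaluate_accuracy(net, dataset)
  lesioned <- evaluate_accuracy(knockout(net, nodes), dataset)
  if (measure == "recall") {
    intact$recall[[as.character(class)]] - lesioned$recall[[as.character(class)]]
  } else {
    intact$overall - lesioned$overall
  }
}

#' Knockout panel along greedy trajectories
#'
#' For every class trace, every relay set YR visited by the greedy search
#' (sizes N down to 1; the empty set is excluded as its effect is 0 by
#' definition) is knocked out and scored, pairing each set's particular
#' relay information with its causal knockout effect. This is the data panel
#' behind the size-versus-information regression.
#'
#' @param net A [relay_network()].
#' @param dataset A [labeled_dataset()].
#' @param traces Named list of `removal_trace` objects, one per class; names
#'   are the class labels (as produced by [attribution_report()]).
#' @param measure Passed to [knockout_effect()].
#' @return Data frame with one row per (class, set): `class`, `size`,
#'   `info` (I_R(i) of the set, bits), `effect` (K), `nodes`
#'   (`+`-separated indices).
#' @export
build_knockout_panel <- function(net, dataset, traces,
                                 measure = c("recall", "overall")) {
  measure <- match.arg(measure)
  if (is.null(names(traces)) || any(!nzchar(names(traces)))) {
    stop("`traces` must be a named list (names = class labels)")
  }
  rows <- list()
  for (cl_name in names(traces)) {
    cl <- as.integer(cl_name)
    tr <- traces[[cl_name]]
    sets <- .trace_sets(tr)
    for (k in seq_along(sets$sets)) {
      nodes <- sets$sets[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl,
        size = length(nodes),
        info = sets$ir[k],
        effect = knockout_effect(net, dataset, nodes, cl, measure = measure),
        nodes = paste(sort(nodes), collapse = "+")
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of knockout effect on set size and relay information
#'
#' Ordinary least squares of the knockout effect K on the set size |YR| and
#' the particular relay information I_R(i), both z-scored by default so the
#' two coefficients are directly comparable. Each predictor's explanatory
#' power is reported as the r-squared of its own single-predictor fit, and
#' the two single-predictor models are compared by the ratio of their
#' residual variances (an F statistic on equal degrees of freedom; values
#' above 1 favour the information model, with p from the F distribution).
#'
#' @param panel Data frame from [build_knockout_panel()] (columns `size`,
#'   `info`, `effect`), or any data frame with those columns.
#' @param standardize Z-score the predictors before the joint fit
#'   (default TRUE). Set FALSE to read raw slopes, e.g. to recover a planted
#'   linear relation in original units.
#' @return An object of class `relay_regression`: list with `n`,
#'   `coefficients` (joint fit: size and info), `se` (their standard
#'   errors), `r2_size`, `r2_info` (single-predictor fits), `f_statistic`,
#'   `p_value`, and `flags` (zero-variance predictors, if any).
#' @export
regression_analysis <- function(panel, standardize = TRUE) {
  need <- c("size", "info", "effect")
  if (!all(need %in% names(panel))) {
    stop("`panel` must contain columns size, info, effect")
  }
  if (nrow(panel) < 3L) stop("at least 3 records are required")
  flags <- character(0)
  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  size_ok <- stats::sd(panel$size) > 0
  info_ok <- stats::sd(panel$info) > 0
  if (!size_ok) flags <- c(flags, "size predictor has zero variance")
  if (!info_ok) flags <- c(flags, "info predictor has zero variance")
  d <- data.frame(
    effect = panel$effect,
    size = if (standardize && size_ok) zscore(panel$size) else panel$size,
    info = if (standardize && info_ok) zscore(panel$info) else panel$info
  )
  n <- nrow(d)
  coefs <- c(size = NA_real_, info = NA_real_)
  ses <- c(size = NA_real_, info = NA_real_)
  if (size_ok && info_ok) {
    joint <- stats::lm(effect ~ size + info, data = d)
    sm <- summary(joint)$coefficients
    coefs[] <- sm[c("size", "info"), "Estimate"]
    ses[] <- sm[c("size", "info"), "Std. Error"]
  }
  r2 <- function(f) summary(f)$r.squared
  fit_size <- if (size_ok) stats::lm(effect ~ size, data = d) else NULL
  fit_info <- if (info_ok) stats::lm(effect ~ info, data = d) else NULL
  r2_size <- if (size_ok) r2(fit_size) else NA_real_
  r2_info <- if (info_ok) r2(fit_info) else NA_real_
  f_statistic <- p_value <- NA_real_
  if (size_ok && info_ok) {
    rss_size <- sum(stats::residuals(fit_size)^2)
    rss_info <- sum(stats::residuals(fit_info)^2)
    df <- n - 2L
    f_statistic <- (rss_size / df) / (rss_info / df)
    p_value <- stats::pf(f_statistic, df, df, lower.tail = FALSE)
  }
  structure(
    list(n = n, coefficients = coefs, se = ses,
         r2_size = r2_size, r2_info = r2_info,
         f_statistic = f_statistic, p_value = p_value,
         standardized = standardize, flags = flags),
    class = "relay_regression"
  )
}

#' @export
print.relay_regression <- function(x, ...) {
  cat(sprintf("<relay_regression> n = %d%s\n", x$n,
              if (x$standardized) " (z-scored predictors)" else ""))
  cat(sprintf("  coefficients: size = %.4f (se %.4f), info = %.4f (se %.4f)\n",
              x$coefficients[["size"]], x$se[["size"]],
              x$coefficients[["info"]], x$se[["info"]]))
  cat(sprintf("  single-predictor r2: size = %.3f, info = %.3f\n",
              x$r2_size, x$r2_info))
  cat(sprintf("  F (size vs info residual variance) = %.3f, p = %.3g\n",
              x$f_statistic, x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
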