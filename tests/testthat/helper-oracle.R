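# Independent brute-force oracle for the information measures.
#
# Deliberately computed along a different path than the package: the full
# joint probability table over all selected columns is materialized with
# interaction()/tapply(), marginals are taken by apply() over array margins,
# and the conditional co-information is assembled as a probability-weighted
# sum of per-slice co-informations, each computed as I(X;Y) - I(X;Y|Z).

oracle_joint_p <- function(cols, w) {
  df <- as.data.frame(cols)
  f <- interaction(df, drop = TRUE, lex.order = TRUE)
  p <- tapply(w, f, sum)
  p[is.na(p)] <- 0
  as.vector(p)
}

oracle_entropy <- function(cols, w) {
  if (is.null(dim(cols))) cols <- matrix(cols, ncol = 1L)
  if (ncol(cols) == 0L) return(0)
  p <- oracle_joint_p(cols, w)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi <- function(x, y, w) {
  oracle_entropy(x, w) + oracle_entropy(y, w) - oracle_entropy(cbind(x, y), w)
}

# conditional MI via E_z[ I(X;Y | Z = z) ], each slice from scratch
oracle_cmi <- function(x, y, z, w) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  if (ncol(z) == 0L) return(oracle_mi(x, y, w))
  key <- apply(z, 1L, paste, collapse = "/")
  out <- 0
  for (v in unique(key)) {
    idx <- key == v
    pz <- sum(w[idx])
    if (pz <= 0) next
    out <- out + pz * oracle_mi(
      if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE],
      if (is.null(dim(y))) y[idx] else y[idx, , drop = FALSE],
      w[idx] / pz
    )
  }
  out
}

# co-information as I(X;Y) - I(X;Y|Z); conditional version conditions both
oracle_coinfo <- function(x, y, z, w, given = NULL) {
  if (is.null(given) || (is.matrix(given) && ncol(given) == 0L)) {
    oracle_mi(x, y, w) - oracle_cmi(x, y, z, w)
  } else {
    zc <- if (is.null(dim(z))) matrix(z, ncol = 1L) else z
    gc <- if (is.null(dim(given))) matrix(given, ncol = 1L) else given
    oracle_cmi(x, y, gc, w) - oracle_cmi(x, y, cbind(zc, gc), w)
  }
}

oracle_relay <- function(table, relay, condition = integer(0), class = NULL) {
  if (!length(relay)) return(0)
  w <- if (is.null(table$weight)) {
    rep(1 / length(table$input_label), length(table$input_label))
  } else {
    table$weight
  }
  if (is.null(class)) {
    x <- table$input_label
    y <- table$predicted_label
  } else {
    x <- as.integer(table$input_label == class)
    y <- as.integer(table$predicted_label == class)
  }
  oracle_coinfo(x, y, table$hidden_bits[, relay, drop = FALSE], w,
                given = table$hidden_bits[, condition, drop = FALSE])
}

# exhaustive per-size maxima computed with the oracle only
oracle_best_per_size <- function(table, class = NULL) {
  n <- ncol(table$hidden_bits)
  vapply(seq_len(n), function(size) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    max(vapply(subsets, function(s) {
      oracle_relay(table, s, setdiff(seq_len(n), s), class)
    }, numeric(1)))
  }, numeric(1))
}
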