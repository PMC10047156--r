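#' Training configuration
#'
#' Mini-batch Adam on mean squared error against one-hot targets coded in the
#' tanh range (+1 for the true class, -1 elsewhere). Training stops at the
#' first epoch whose overall accuracy reaches `target_accuracy`, or at
#' `max_epochs`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on training epochs (>= 1).
#' @param target_accuracy Accuracy in (0, 1\] at which training stops early.
#'   A value of 0 is accepted and stops after the first epoch.
#' @param seed Integer seed; fixes initialization and batch order, so training
#'   is exactly reproducible.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 100L, target_accuracy = 0.95,
                         seed = 1L) {
  if (max_epochs < 1L) stop("`max_epochs` must be at least 1")
  if (target_accuracy < 0 || target_accuracy > 1) {
    stop("`target_accuracy` must lie in [0, 1]")
  }
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         target_accuracy = target_accuracy, seed = as.integer(seed)),
    class = "train_config"
  )
}

.init_weight <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Train a tanh feed-forward network
#'
#' Trains a fresh `inputs - n_hidden - n_out` network on the dataset with
#' mini-batch Adam (beta1 = 0.9, beta2 = 0.999) on MSE against one-hot
#' targets in `{-1, 1}`. With `n_out = 1` the dataset must be binary
#' (one-versus-rest coding; see [as_binary_dataset()]): the target is +1 for
#' class 1 and -1 otherwise, and accuracy uses the sign readout at 0.
#'
#' @param dataset A [labeled_dataset()].
#' @param n_hidden Number of hidden nodes.
#' @param n_out Number of output nodes; defaults to `dataset$n_classes`.
#' @param cfg A [train_config()].
#' @return List with `network` (the trained [relay_network()]) and `history`,
#'   a data frame with one row per epoch: `epoch`, `loss`, `accuracy`, and
#'   one `recall_<class>` column per class.
#' @export
train_network <- function(dataset, n_hidden, n_out = NULL,
                          cfg = train_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(cfg, "train_config"))
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) stop("`n_hidden` must be at least 1")
  if (is.null(n_out)) n_out <- dataset$n_classes
  n_out <- as.integer(n_out)
  if (n_out == 1L && dataset$n_classes != 2L) {
    stop("a single-output network requires a binary dataset (see as_binary_dataset)")
  }
  if (n_out > 1L && n_out != dataset$n_classes) {
    stop("`n_out` must be 1 or equal to the number of classes")
  }

  x <- dataset$features
  n <- nrow(x)
  if (n_out == 1L) {
    targets <- matrix(ifelse(dataset$labels == 1L, 1, -1), ncol = 1L)
  } else {
    targets <- matrix(-1, n, n_out)
    targets[cbind(seq_len(n), dataset$labels + 1L)] <- 1
  }

  set.seed(cfg$seed)
  par <- list(
    w1 = .init_weight(ncol(x), n_hidden), b1 = numeric(n_hidden),
    w2 = .init_weight(n_hidden, n_out), b2 = numeric(n_out)
  )
  m <- lapply(par, function(p) p * 0)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L

  history <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      xb <- x[b, , drop = FALSE]
      tb <- targets[b, , drop = FALSE]
      h <- tanh(.add_bias(xb %*% par$w1, par$b1))
      o <- tanh(.add_bias(h %*% par$w2, par$b2))
      err <- o - tb
      if (any(!is.finite(err))) stop("training diverged: non-finite loss")
      epoch_loss <- epoch_loss + sum(err^2)
      g_o <- (2 / length(err)) * err * (1 - o^2)
      grad <- list(
        w1 = NULL, b1 = NULL,
        w2 = crossprod(h, g_o), b2 = colSums(g_o)
      )
      g_h <- (g_o %*% t(par$w2)) * (1 - h^2)
      grad$w1 <- crossprod(xb, g_h)
      grad$b1 <- colSums(g_h)
      t <- t + 1L
      for (k in names(par)) {
        m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grad[[k]]
        v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grad[[k]]^2
        m_hat <- m[[k]] / (1 - beta1^t)
        v_hat <- v[[k]] / (1 - beta2^t)
        par[[k]] <- par[[k]] - cfg$learning_rate * m_hat / (sqrt(v_hat) + eps)
      }
    }
    net <- relay_network(list(par$w1, par$w2), list(par$b1, par$b2))
    acc <- evaluate_accuracy(net, dataset)
    row <- data.frame(epoch = epoch, loss = epoch_loss / n,
                      accuracy = acc$overall)
    for (cl in names(acc$recall)) row[[paste0("recall_", cl)]] <- acc$recall[[cl]]
    history[[epoch]] <- row
    if (acc$overall >= cfg$target_accuracy) break
  }
  list(network = net, history = do.call(rbind, history[!vapply(history, is.null, TRUE)]))
}

#' Train a one-versus-rest sub-network
#'
#' Convenience wrapper: relabels the dataset to "class versus rest" (keeping
#' the native class imbalance), trains an `inputs - n_hidden - 1` network,
#' and tags the result with the target class.
#'
#' @param dataset A multi-class [labeled_dataset()].
#' @param class Target class (0-based).
#' @param n_hidden Number of hidden nodes (default 2).
#' @param cfg A [train_config()].
#' @return As [train_network()]; the network carries a `target_class` attribute.
#' @export
train_subnetwork <- function(dataset, class, n_hidden = 2L,
                             cfg = train_config(target_accuracy = 0.98)) {
  bin <- as_binary_dataset(dataset, class)
  out <- train_network(bin, n_hidden = n_hidden, n_out = 1L, cfg = cfg)
  attr(out$network, "target_class") <- as.integer(class)
  out
}

#' Compose one-output sub-networks into a composite network
#'
#' Assembles C single-output sub-networks (one per class, in class order)
#' into one `inputs - C*m - C` network, where m is the common hidden size of
#' the sub-networks (2 in the standard construction). The hidden nodes of
#' sub-network i occupy slots `(i-1)*m + 1 .. i*m`; its hidden-to-output
#' weights connect only those slots to output i, and every cross entry of the
#' composite second-layer matrix is exactly 0.0, so that matrix is de facto
#' sparse. Biases are carried over unchanged and no further training occurs.
#'
#' @param subnets List of [relay_network()] objects, each with one output
#'   node, identical input size and identical hidden size.
#' @return A composite `relay_network` with attribute `relay_map`, a list
#'   mapping class label (as character) to its hidden slot indices.
#' @export
compose_networks <- function(subnets) {
  if (!is.list(subnets) || length(subnets) < 2L) {
    stop("`subnets` must be a list of at least two sub-networks")
  }
  sizes <- vapply(subnets, layer_sizes, integer(3))
  if (any(sizes[3L, ] != 1L)) stop("every sub-network must have exactly one output node")
  if (length(unique(sizes[1L, ])) != 1L) stop("sub-networks must share the input size")
  if (length(unique(sizes[2L, ])) != 1L) stop("sub-networks must share the hidden size")
  k <- length(subnets)
  m <- sizes[2L, 1L]
  w1 <- do.call(cbind, lapply(subnets, function(s) s$weights[[1L]]))
  b1 <- unlist(lapply(subnets, function(s) s$biases[[1L]]), use.names = FALSE)
  w2 <- matrix(0, k * m, k)
  for (i in seq_len(k)) {
    slots <- ((i - 1L) * m + 1L):(i * m)
    w2[slots, i] <- subnets[[i]]$weights[[2L]][, 1L]
  }
  b2 <- vapply(subnets, function(s) s$biases[[2L]][1L], numeric(1))
  net <- relay_network(list(w1, w2), list(b1, b2))
  relay_map <- lapply(seq_len(k), function(i) ((i - 1L) * m + 1L):(i * m))
  names(relay_map) <- as.character(seq_len(k) - 1L)
  attr(net, "relay_map") <- relay_map
  net
}
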