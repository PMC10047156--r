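# Small table builders shared across tests. Everything is generated in code;
# no stored fixtures.

# a perfect balanced C-class classifier: predicted == label, one constant
# hidden bit so the table is well-formed
perfect_channel_table <- function(n_classes = 10L, n_per_class = 5L) {
  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  discrete_state_table(labels, labels,
                       matrix(0L, length(labels), 1L),
                       n_classes = n_classes)
}

# a 1-bit perfect channel: fair input bit, output a copy, hidden bits given
# as columns of `bits` (defaults to a single perfect relay bit)
fair_bit_table <- function(bits = NULL, n = 8L) {
  z <- rep(0:1, each = n / 2)
  if (is.null(bits)) bits <- matrix(z, ncol = 1L)
  discrete_state_table(z, z, bits, n_classes = 2L)
}

# state_table builder for discretization tests
make_state_table <- function(activations, labels = NULL, predicted = NULL,
                             n_classes = 2L) {
  activations <- as.matrix(activations)
  n <- nrow(activations)
  if (is.null(labels)) labels <- rep(0L, n)
  if (is.null(predicted)) predicted <- labels
  structure(
    list(input_label = as.integer(labels),
         predicted_label = as.integer(predicted),
         activations = activations, n_classes = as.integer(n_classes)),
    class = "state_table"
  )
}

# the planted composite network experiment used by several test files
planted_experiment <- function(n_classes = 4L, n_features = 16L, n = 1200L,
                               n_inert = 2L, noise = 0.02, seed = 7L) {
  dataset <- generate_pattern_dataset(n_classes, n_features, n,
                                      noise = noise, seed = seed)
  planted <- make_planted_relay_network(n_classes, n_features,
                                        n_inert = n_inert)
  states <- record_states(planted$network, dataset)
  table <- suppressMessages(binarize(states, fit_binarizer(states)))
  list(dataset = dataset, planted = planted, states = states, table = table)
}

binary_entropy <- function(p) {
  p <- p[p > 0 & p < 1]
  if (!length(p)) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

greedy_per_size_ir <- function(trace) rev(relaytrace:::.trace_sets(trace)$ir)
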