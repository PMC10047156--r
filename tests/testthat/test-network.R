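test_that("network construction validates layer conformance", {
  w1 <- matrix(0, 4, 3); w2 <- matrix(0, 3, 2)
  net <- relay_network(list(w1, w2), list(numeric(3), numeric(2)))
  expect_equal(layer_sizes(net), c(4L, 3L, 2L))
  expect_error(relay_network(list(w1, matrix(0, 4, 2)),
                             list(numeric(3), numeric(2))),
               "conformant")
  expect_error(relay_network(list(w1, w2), list(numeric(2), numeric(2))),
               "bias")
})

test_that("argmax readout breaks ties toward the lowest index", {
  net <- relay_network(list(matrix(0, 2, 2), matrix(0, 2, 3)),
                       list(numeric(2), c(0.5, 0.5, 0.2)))
  expect_equal(predict_labels(net, matrix(0, 5, 2)), rep(0L, 5))
})

test_that("knockout zeroes incident weights and equals activation clamping", {
  set.seed(101)
  net <- relay_network(
    list(matrix(rnorm(32), 8, 4), matrix(rnorm(12), 4, 3)),
    list(rnorm(4), rnorm(3))
  )
  x <- matrix(runif(80, -1, 1), 10, 8)

  # empty lesion is the identity
  expect_identical(forward_pass(knockout(net, integer(0)), x),
                   forward_pass(net, x))

  # clamp-equivalence holds bit-exactly for every node set
  for (nodes in list(2L, c(1L, 3L), 1:4)) {
    ko <- forward_pass(knockout(net, nodes), x)
    cl <- forward_pass(net, x, clamp = nodes)
    expect_identical(ko$output, cl$output)
    expect_identical(ko$hidden, cl$hidden)
  }

  # lesioning everything leaves a constant network: tanh of the output biases
  all_out <- forward_pass(knockout(net, 1:4), x)$output
  expect_equal(unique(round(all_out, 12)),
               matrix(round(tanh(net$biases[[2]]), 12), 1),
               ignore_attr = TRUE)
  expect_length(unique(predict_labels(knockout(net, 1:4), x)), 1L)

  expect_error(knockout(net, 9L), "out of range")
})

test_that("composition wires sub-networks into disjoint hidden blocks", {
  set.seed(5)
  subnets <- lapply(1:4, function(i) {
    relay_network(list(matrix(rnorm(16), 8, 2), matrix(rnorm(2), 2, 1)),
                  list(rnorm(2), rnorm(1)))
  })
  comp <- compose_networks(subnets)
  expect_equal(layer_sizes(comp), c(8L, 8L, 4L))
  # exactly 2 nonzero entries per output column: the weight matrix is sparse
  expect_equal(sum(comp$weights[[2]] != 0), 8L)
  # block structure: sub-net i feeds only output i from slots (2i-1, 2i)
  for (i in 1:4) {
    slots <- (2 * i - 1):(2 * i)
    expect_equal(comp$weights[[2]][slots, i],
                 subnets[[i]]$weights[[2]][, 1])
    expect_true(all(comp$weights[[2]][-slots, i] == 0))
  }

  # identical sub-nets give identical output activations on any input
  same <- compose_networks(rep(subnets[1], 4))
  out <- forward_pass(same, matrix(runif(24, -1, 1), 3, 8))$output
  expect_equal(out[, 1], out[, 2])
  expect_equal(out[, 1], out[, 4])

  # composition locality: perturbing foreign hidden slots leaves output i
  # unchanged
  x <- matrix(runif(40, -1, 1), 5, 8)
  base <- forward_pass(comp, x)$output
  for (i in 1:4) {
    foreign <- setdiff(1:8, (2 * i - 1):(2 * i))
    pert <- forward_pass(comp, x, clamp = foreign)$output
    expect_equal(pert[, i], base[, i])
  }

  # knocking out sub-net i's slots freezes output i, leaves the rest intact
  ko <- forward_pass(knockout(comp, 3:4), x)$output
  expect_length(unique(round(ko[, 2], 12)), 1L)
  expect_equal(ko[, -2], base[, -2])

  expect_error(compose_networks(subnets[1]), "at least two")
  bad <- relay_network(list(matrix(0, 8, 2), matrix(0, 2, 2)),
                       list(numeric(2), numeric(2)))
  expect_error(compose_networks(list(subnets[[1]], bad)), "one output")
})

test_that("record_states aligns labels, predictions and activations", {
  exp_ <- planted_experiment(n = 300L, noise = 0, seed = 3L)
  st <- record_states(exp_$planted$network, exp_$dataset)
  expect_equal(length(st$input_label), 300L)
  expect_equal(dim(st$activations),
               c(300L, layer_sizes(exp_$planted$network)[2]))
  expect_true(all(abs(st$activations) <= 1))
  # noise-free patterns: the planted composite classifies perfectly
  expect_equal(st$predicted_label, st$input_label)

  # an all-zero network records identical tanh(bias) rows
  zero <- relay_network(list(matrix(0, 16, 3), matrix(0, 3, 4)),
                        list(c(0.3, -0.2, 0), numeric(4)))
  st0 <- record_states(zero, exp_$dataset)
  expect_equal(st0$activations,
               matrix(tanh(c(0.3, -0.2, 0)), 300, 3, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("accuracy evaluation reports overall and per-class recall", {
  labels <- rep(0:3, each = 5)
  feats <- matrix(0, 20, 2)
  data <- labeled_dataset(feats, labels, n_classes = 4L)
  # constant network predicting class 2 on balanced 4-class data
  net <- relay_network(list(matrix(0, 2, 2), matrix(0, 2, 4)),
                       list(numeric(2), c(0, 0, 1, 0)))
  acc <- evaluate_accuracy(net, data)
  expect_equal(acc$overall, 0.25)
  expect_equal(unname(acc$recall), c(0, 0, 1, 0))
  # a class absent from the data has undefined recall
  data3 <- labeled_dataset(feats, labels, n_classes = 5L)
  expect_true(is.na(evaluate_accuracy(net, data3)$recall[["4"]]))
})
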