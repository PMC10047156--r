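test_that("joint entropy matches closed forms on elementary columns", {
  expect_equal(joint_entropy(c(0, 0, 1, 1)), 1.0)
  expect_equal(joint_entropy(rep(3, 10)), 0.0)
  two_bits <- cbind(rep(0:1, each = 2), rep(0:1, times = 2))
  expect_equal(joint_entropy(two_bits), 2.0)
  # weighted (exact-distribution) form
  expect_equal(joint_entropy(c(0, 1), weights = c(0.5, 0.5)), 1.0)
  expect_equal(joint_entropy(c(0, 1), weights = c(0.25, 0.75)),
               binary_entropy(0.25))
})

test_that("joint entropy is bounded by the log-count of observed tuples", {
  set.seed(31)
  for (i in 1:20) {
    cols <- matrix(sample(0:2, 40, replace = TRUE), ncol = 2)
    h <- joint_entropy(cols)
    k <- nrow(unique(cols))
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
  }
})

test_that("Miller-Madow correction is exposed but off by default", {
  x <- c(0, 0, 1, 1, 1, 2)
  h <- joint_entropy(x)
  hmm <- joint_entropy(x, correction = "miller-madow")
  expect_equal(hmm - h, (3 - 1) / (2 * 6 * log(2)))
  expect_error(joint_entropy(x, weights = rep(1 / 6, 6),
                             correction = "miller-madow"),
               "equally-weighted")
})

test_that("mutual information follows the entropy identity and is symmetric", {
  # perfect balanced 10-class channel carries log2(10) bits
  tab <- perfect_channel_table(10L, 4L)
  expect_equal(mutual_information(tab$input_label, tab$predicted_label),
               log2(10))
  # independent columns (full product design)
  x <- rep(0:1, each = 4); y <- rep(0:1, times = 4)
  expect_equal(mutual_information(x, y), 0.0)
  # deterministic copy
  z <- sample(0:2, 30, replace = TRUE)
  expect_equal(mutual_information(z, z), joint_entropy(z))
  # symmetry
  set.seed(5)
  a <- sample(0:1, 50, TRUE); b <- sample(0:2, 50, TRUE)
  expect_equal(mutual_information(a, b), mutual_information(b, a))
})

test_that("co-information matches hand values and is permutation invariant", {
  x <- rep(0:1, each = 2)
  # copy chain: all three variables identical
  expect_equal(co_information(x, x, x), 1.0)
  # xor: pairwise independent, jointly determined
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1); c <- bitwXor(a, b)
  expect_equal(co_information(a, b, c), -1.0)
  # any constant argument kills the triplet information
  expect_equal(co_information(a, b, rep(0, 4)), 0.0)
  # permutation invariance
  set.seed(8)
  u <- sample(0:1, 60, TRUE); v <- sample(0:1, 60, TRUE)
  w <- as.integer(xor(u, v) | sample(0:1, 60, TRUE))
  base <- co_information(u, v, w)
  expect_equal(co_information(v, w, u), base)
  expect_equal(co_information(w, u, v), base)
})

test_that("relay information respects its conventions and reductions", {
  # conditioning on a constant bit is a no-op: perfect 1-bit relay
  tab <- fair_bit_table(bits = cbind(rep(0:1, each = 4), 0L))
  expect_equal(relay_information(tab, relay = 1L, condition = 2L), 1.0)
  # a Y0 that copies the single-node YR shields everything: all conditional
  # terms vanish
  tab2 <- fair_bit_table(bits = cbind(rep(0:1, each = 4), rep(0:1, each = 4)))
  expect_equal(relay_information(tab2, relay = 1L, condition = 2L), 0.0)
  # empty relay set carries nothing by convention
  expect_equal(relay_information(tab, relay = integer(0), condition = 1:2), 0)
  # empty conditioning reduces exactly to the triplet co-information
  set.seed(13)
  bits <- matrix(sample(0:1, 200, TRUE), ncol = 4)
  lab <- sample(0:2, 50, TRUE)
  pred <- sample(0:2, 50, TRUE)
  t3 <- discrete_state_table(lab, pred, bits, n_classes = 3L)
  expect_equal(relay_information(t3, relay = 1:4),
               co_information(lab, pred, bits))
  # disjointness and range checks
  expect_error(relay_information(t3, relay = 1:2, condition = 2:3), "disjoint")
  expect_error(relay_information(t3, relay = 9L), "out of range")
})

test_that("particular relay information uses per-class indicators", {
  tab <- perfect_channel_table(10L, 4L)
  # H(Z_i) of a balanced 10-class perfect classifier: binary entropy of 0.1
  expect_equal(particular_relay_information(tab, class = 3L, relay = 1L,
                                            condition = integer(0)),
               0, tolerance = 1e-12)  # constant hidden bit carries nothing
  # with the class variable relayed perfectly through a hidden bit
  lab <- rep(0:9, each = 4)
  bits <- cbind(as.integer(lab == 3L))
  t2 <- discrete_state_table(lab, lab, bits, n_classes = 10L)
  expect_equal(particular_relay_information(t2, class = 3L, relay = 1L),
               binary_entropy(0.1))
  # a class that never occurs and is never predicted contributes zero
  lab01 <- rep(0:1, each = 5)
  t3 <- discrete_state_table(lab01, lab01, cbind(lab01), n_classes = 3L)
  expect_equal(particular_relay_information(t3, class = 2L, relay = 1L), 0.0)
  expect_error(particular_relay_information(t3, class = 7L, relay = 1L),
               "class")
})

test_that("information measures agree with the brute-force oracle", {
  for (enc in c("and", "xor")) {
    tab <- exact_relay_table(encoding = enc, n_junk = 2L, n_inert = 1L)
    n <- n_hidden_nodes(tab)
    set.seed(17)
    for (i in 1:15) {
      relay <- sort(sample(n, sample(n - 1L, 1L)))
      rest <- setdiff(seq_len(n), relay)
      cond <- if (runif(1) < 0.5) rest else sample(rest, length(rest) %/% 2)
      for (cl in list(NULL, 1L)) {
        expect_equal(relay_information(tab, relay, cond, class = cl),
                     oracle_relay(tab, relay, cond, class = cl),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the full hidden layer of a deterministic channel carries I(Xin;Xout)", {
  # predicted label is a deterministic function of the hidden bits, so the
  # triplet co-information with the whole layer equals the channel information
  te <- exact_relay_table(n_classes = 3L, detect_classes = 0:2,
                          fidelity = 0.9, false_rate = 0.05)
  expect_equal(
    relay_information(te, seq_len(n_hidden_nodes(te))),
    mutual_information(te$input_label, te$predicted_label,
                       weights = te$weight),
    tolerance = 1e-12
  )
  exp_ <- planted_experiment(n = 600L, seed = 21L)
  tab <- exp_$table
  expect_equal(
    relay_information(tab, seq_len(n_hidden_nodes(tab))),
    mutual_information(tab$input_label, tab$predicted_label),
    tolerance = 1e-9
  )
})
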