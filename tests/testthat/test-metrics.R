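test_that("information deltas telescope exactly to the full-set relay information", {
  set.seed(23)
  bits <- matrix(sample(0:1, 300 * 6, TRUE), 300, 6)
  lab <- sample(0:2, 300, TRUE)
  pred <- ifelse(runif(300) < 0.8, lab, sample(0:2, 300, TRUE))
  tab <- discrete_state_table(lab, pred, bits, n_classes = 3L)
  tr <- greedy_shrink(tab)
  d <- suppressWarnings(delta_information(tr))
  expect_equal(sum(d$delta), tr$ir_full, tolerance = 1e-12)
  agg <- suppressWarnings(aggregated_relay_information(tr))
  # the last removed node accumulates the whole relay information
  expect_equal(agg$aggregated[nrow(agg)], tr$ir_full, tolerance = 1e-12)
  expect_equal(agg$aggregated, cumsum(d$delta))
})

test_that("inert nodes lose nothing; planted relays carry all the loss", {
  tab <- exact_relay_table(n_junk = 2L, n_inert = 2L)
  pair <- attr(tab, "relay_map")[["1"]]
  inert <- attr(tab, "inert_nodes")
  tr <- greedy_shrink(tab)
  d <- delta_information(tr)
  # inert (constant) nodes: exactly zero loss at their removal step
  expect_true(all(d$delta[d$node %in% inert] == 0))
  # junk nodes: zero up to numerical noise
  nonrelay <- setdiff(seq_len(n_hidden_nodes(tab)), pair)
  expect_true(all(abs(d$delta[d$node %in% nonrelay]) < 1e-9))
  # only the relay pair loses information
  expect_true(all(d$delta[d$node %in% pair] > 0.1))
  # a node with zero loss removed first accumulates nothing
  agg <- aggregated_relay_information(tr)
  expect_equal(agg$aggregated[1], 0, tolerance = 1e-12)

  # incomplete traces are rejected
  broken <- tr
  broken$steps <- broken$steps[-1, ]
  expect_error(delta_information(broken), "incomplete")
})

test_that("essentiality is the single-removal information loss from the full set", {
  # sole relay of a 1-bit perfect channel is fully essential
  tab <- fair_bit_table()
  expect_equal(unname(essentiality(tab)), 1.0)

  # direct definition check against relay_information
  tab2 <- exact_relay_table(n_junk = 1L, n_inert = 1L)
  n <- n_hidden_nodes(tab2)
  ir_full <- relay_information(tab2, seq_len(n))
  ess <- essentiality(tab2)
  for (j in seq_len(n)) {
    expect_equal(ess[[as.character(j)]],
                 ir_full - relay_information(tab2, setdiff(seq_len(n), j), j),
                 tolerance = 1e-12)
  }
  # conjunctive relay members are individually essential, junk/inert are not
  pair <- attr(tab2, "relay_map")[["1"]]
  expect_true(all(ess[pair] > 0.1))
  expect_true(all(abs(ess[-pair]) < 1e-9))
  expect_error(essentiality(tab2, nodes = 99L), "out of range")
})

test_that("parity-coded relays and their copies have zero essentiality", {
  # each member of an xor pair is marginally independent of input and output,
  # so the single-removal loss vanishes although the pair is essential as a
  # set; a redundant copy of such a member inherits the zero
  tab <- exact_relay_table(encoding = "xor", n_junk = 1L, n_inert = 0L,
                           redundancy = 1L)
  pair <- attr(tab, "relay_map")[["1"]]
  copy <- attr(tab, "redundant_nodes")
  ess <- essentiality(tab)
  expect_equal(unname(ess[pair]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(ess[copy]), 0, tolerance = 1e-12)
  # yet the pair still relays everything: the channel is intact
  expect_gt(relay_information(tab, pair, setdiff(seq_len(n_hidden_nodes(tab)),
                                                 pair)), 0.3)
})

test_that("ranking nodes by aggregated information recovers planted relays", {
  for (s in c(2L, 5L)) {
    tab <- random_exact_relay_table(s)
    pair <- attr(tab, "relay_map")[["1"]]
    agg <- aggregated_relay_information(greedy_shrink(tab, class = 1L))
    # order by aggregated loss, break ties by removal step (later = more)
    top2 <- agg$node[order(-agg$aggregated, -agg$step)][1:2]
    expect_setequal(top2, pair)
  }
})

test_that("attribution reports assemble node-by-class matrices", {
  exp_ <- planted_experiment(n = 800L, seed = 31L)
  tab <- exp_$table
  rep_ <- attribution_report(tab)
  nh <- n_hidden_nodes(tab)
  expect_equal(dim(rep_$aggregated), c(nh, 4L))
  expect_equal(dim(rep_$essentiality), c(nh, 4L))
  # every column of the rank matrix is a permutation of the steps
  for (j in 1:4) expect_setequal(rep_$rank[, j], seq_len(nh))
  # essentiality singles out the planted pair of each class
  for (cl in as.character(0:3)) {
    pair <- exp_$planted$relay_map[[cl]]
    top2 <- sort(order(rep_$essentiality[, cl], decreasing = TRUE)[1:2])
    expect_equal(top2, pair)
  }
  # the planted pair attains the column maximum of aggregated information
  for (cl in as.character(0:3)) {
    pair <- exp_$planted$relay_map[[cl]]
    colmax <- max(rep_$aggregated[, cl])
    expect_true(all(rep_$aggregated[pair, cl] >= colmax - 1e-6))
  }
})
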