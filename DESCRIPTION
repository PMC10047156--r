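Package: relaytrace
Title: Relay Information and Functional Module Detection in Feed-Forward
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates functional modules in small feed-forward neural networks
    by measuring how much input-to-output class information is relayed through
    subsets of hidden nodes. Implements plug-in discrete entropy and
    (conditional) co-information estimation, the relay information of a hidden
    bipartition, a greedy shrinking subset aggregation search for minimal
    informative node sets alongside an exhaustive bipartition oracle,
    per-node attribution (information loss, aggregated relay information,
    essentiality), and causal validation by knockout analysis with a
    size-versus-information regression. Includes trainable tanh networks with
    an argmax readout, composition of one-versus-rest sub-networks into a
    composite control with known ground-truth relays, per-neuron two-cluster
    coarse-graining of hidden activations, and synthetic fixture generators
    (planted-relay networks, separable pattern datasets, and analytically
    exact joint state tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
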