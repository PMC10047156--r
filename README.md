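# relaytrace

Which hidden nodes of a trained classifier actually carry a given class's
information from input to output? `relaytrace` answers this for small
feed-forward tanh networks with an information-theoretic attribution
measure — **relay information** — plus a quadratic-cost greedy search for
minimal informative node sets, and causal validation by knockout analysis.

## The measure

View the network as a channel: true class `X_in`, predicted class `X_out`,
hidden layer `Y = Y_R ⊗ Y_0` split into a candidate relay set and its
complement. The relay information of `Y_R` is the triplet co-information
conditioned on the complement,

    I_R = I(X_in ; X_out ; Y_R | Y_0)
        = H(X_in|Y_0) + H(X_out|Y_0) + H(Y_R|Y_0)
        − H(X_in,X_out|Y_0) − H(X_in,Y_R|Y_0) − H(X_out,Y_R|Y_0)
        + H(X_in,X_out,Y_R|Y_0),

estimated with plug-in discrete entropies (base 2) after per-neuron
two-cluster coarse-graining of the continuous activations. Conditioning on
`Y_0` excludes information that bypasses `Y_R` or is merely copied into it.
The per-class variant `I_R(i)` uses the indicators `[label == i]` and
`[predicted == i]`.

The *shrinking subset aggregation* search starts from the full hidden layer
and repeatedly discards the node whose removal retains the most relay
information — `N(N+1)/2` evaluations instead of `2^N − 1` bipartitions; an
exhaustive search is included as the exact oracle for small layers.
Per-node attribution comes as the step loss `ΔI(n)`, its running sum `I_A(n)`
(aggregated relay information), and the single-removal *essentiality*.
Knockouts (zeroing a node's incident weights, exactly equivalent to
clamping its activation to 0) then test whether informative sets are
causally necessary, via a regression of the recall drop on set size versus
relayed information.

Everything is testable offline: the fixture module generates separable
pattern datasets (orthogonal Hadamard prototypes), composite networks with
*planted* relay pairs and known ground truth, and analytically exact joint
state tables on which the algebraic identities hold to 1e-12.

## Worked example

Four-class pattern task, planted composite network (two relay nodes per
class, two inert nodes), k-means binarization, greedy search, attribution,
knockout regression:

```r
library(relaytrace)

data    <- generate_pattern_dataset(4, 16, 2000, noise = 0.02, seed = 12)
planted <- make_planted_relay_network(4, 16, n_inert = 2)
evaluate_accuracy(planted$network, data)$overall
#> [1] 0.984

states <- record_states(planted$network, data)
table  <- binarize(states, fit_binarizer(states))
mutual_information(table$input_label, table$predicted_label)
#> [1] 1.860697        # channel information, bits (log2(4) = 2 is the ceiling)

greedy_shrink(table, class = 1)
#> <removal_trace> 10 nodes (class 1), I_R(full) = 0.7205 bits, 55 evaluations
#> removal order: 9 10 5 6 1 2 3 4 7 8

round(attribution_report(table)$essentiality, 3)
#>     class
#> node     0     1     2     3
#>   1  0.741 0.103 0.119 0.107
#>   2  0.741 0.103 0.119 0.107
#>   3  0.107 0.720 0.114 0.106
#>   4  0.107 0.720 0.114 0.106
#>   5  0.123 0.102 0.771 0.122
#>   6  0.123 0.102 0.771 0.122
#>   7  0.107 0.109 0.126 0.752
#>   8  0.107 0.109 0.126 0.752
#>   9  0.000 0.000 0.000 0.000
#>   10 0.000 0.000 0.000 0.000
```

The planted pairs sit exactly on the diagonal of the essentiality matrix:
nodes (1,2) carry class 0, (3,4) class 1, and so on; the two inert nodes
attribute to zero. The inert nodes are also the first two removed by the
greedy trace above, at zero information cost. Knockouts confirm the
informational picture causally:

```r
report <- attribution_report(table)
panel  <- build_knockout_panel(planted$network, data, report$traces)
regression_analysis(panel)
#> <relay_regression> n = 40 (z-scored predictors)
#>   coefficients: size = -0.2016 (se 0.1434), info = 0.4661 (se 0.1434)
#>   single-predictor r2: size = 0.275, info = 0.406
#>   F (size vs info residual variance) = 1.221, p = 0.271
```

The knockout effect follows the relayed information, not the number of
nodes lesioned. `run_pipeline(pipeline_config(out_dir = "out"))` executes
the same chain end to end and writes every table, trace and summary (plus a
checksummed manifest) to disk; see the vignette
(`vignettes/relay-information.Rmd`) for the model, its assumptions, and the
design choices.

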