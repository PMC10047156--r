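---
title: "Relay information: locating functional modules in feed-forward networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relay information: locating functional modules in feed-forward networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaytrace)
```

## The problem

A trained feed-forward classifier is an information channel: the class
identity enters at the input layer, passes through the hidden layer, and
re-emerges as a predicted label. Which hidden nodes actually carry a given
class's information? Activation magnitudes and weights do not answer this —
a node can be busy without being informative, informative without being
used, or redundant with other nodes so that lesioning it changes nothing.
`relaytrace` answers the question information-theoretically and then checks
the answer causally with knockouts.

## The measure

Write $X_{in}$ for the true class, $X_{out}$ for the predicted class, and
$Y = Y_R \otimes Y_0$ for a bipartition of the (discretized) hidden layer
into a candidate relay set and its complement. The channel information is
the mutual information

$$I(X_{in};X_{out}) = H(X_{in}) + H(X_{out}) - H(X_{in},X_{out}),$$

and because every bit of it must traverse the hidden layer, the triplet
co-information $I(X_{in};X_{out};Y)$ (the seven-term inclusion–exclusion
over the three groups) equals $I(X_{in};X_{out})$ whenever the prediction is
a deterministic function of the hidden state. The **relay information** of a
subset $Y_R$ is the same triplet co-information with every entropy term
conditioned on the complement:

$$I_R = I(X_{in};X_{out};Y_R \mid Y_0).$$

Conditioning on $Y_0$ is what makes the measure attributive: information
that is also visible in $Y_0$ (for example through an inert node that
merely copies a relay neuron) is excluded, so a $Y_0$ that duplicates $Y_R$
drives $I_R$ to zero. The **particular relay information** $I_R(i)$ replaces
the class variables by the binary indicators "true label is $i$" and
"predicted label is $i$", restricting the measure to one class's channel.

All entropies are plug-in (maximum-likelihood) estimates in base 2 over the
empirically realized joint states only; we deliberately apply no bias
correction, because the quantities of interest here live on a
low-entropy input variable where the plug-in bias is small, and because
corrections would break the exact identities the test suite relies on. A
Miller–Madow option exists behind a flag for users who want it.

## Finding minimal informative sets

Scanning all $2^N - 1$ bipartitions is exponential;
[exhaustive_search()] does it anyway for small layers and serves as the
oracle. The **shrinking subset aggregation** search ([greedy_shrink()])
starts from the full layer and repeatedly moves the node whose removal
*retains* the most relay information into the conditioning set, until the
relay set is empty. This costs exactly $N(N+1)/2$ evaluations. Ties are
broken toward the lowest node index so runs are deterministic. The
[minimal_set()] of a trajectory is the smallest visited set whose relay
information is still at least $(1-\varepsilon)$ of the full-layer value;
"minimal" is not otherwise operationalized by the measure itself, so the
relative threshold (default $\varepsilon = 0.05$) is exposed everywhere.

Three attribution summaries come from the trace: the per-step loss
$\Delta I(n)$, its running sum $I_A(n)$ (**aggregated relay information**),
and the **essentiality** of a node — the loss when that single node is moved
from the full set into the conditioning set. A useful identity follows
directly from the definitions: essentiality reduces to the *unconditional*
triplet co-information of that one node,
$\mathrm{ess}(n) = I(X_{in};X_{out};n)$. Two consequences matter in
practice:

* a node whose state is individually uninformative — one member of a
  parity-coded pair, or any copy of such a member — has essentiality
  exactly zero even when the pair as a set is indispensable. Single-node
  essentiality under-reports synergistic structure; the aggregated measure
  $I_A$ is the one that exposes such "encrypted" sets.
* a copy of an *individually informative* node does **not** have zero
  essentiality, because the measure depends only on the node's own joint
  statistics with input and output. Redundancy zeroes essentiality only
  through individual uninformativeness, which is how the package's
  redundancy fixtures are built.

## Discretization

Hidden activations are continuous in $[-1,1]$; discrete entropies need
symbols. Each neuron is coarse-grained independently to one bit. The default
fits two centroids by k-means (via `stats::kmeans`) from a deterministic
initialization at the neuron's minimum and maximum — a 1-D two-cluster
problem has no meaningful seed sensitivity, and this choice removes it
entirely. Assignment goes to the nearer centroid, exact ties to the lower
cluster. The median alternative forces a 50/50 split (maximal marginal
entropy), which misrepresents neurons whose activation distribution is
genuinely skewed; k-means tracks the actual shape, which is why it is the
default. Constant neurons cannot be split; they map to bit 0, carry zero
entropy either way, and are flagged. The binarizer is fitted on the same
evaluation set used for entropy estimation.

## Synthetic fixtures and what they do (not) show

The package must be testable without any image downloads, so the fixture
module generates every study condition in code:

* **Pattern datasets** ([generate_pattern_dataset()]): classes are rows of a
  Sylvester Hadamard matrix — orthogonal $\pm 1$ prototypes — plus bounded
  uniform feature noise (half-width 0.3) and a 2% label-flip rate by
  default. Orthogonality makes Bayes-optimal behaviour computable and keeps
  the task linearly separable, which pins the trainer's stopping behaviour.
  The defaults (4 classes, 16 features, 2000 samples) are the desk-scale
  stand-in for a 10-class image task; they preserve the structure of the
  problem (many-class one-hot channel, ~0.98 reachable accuracy) but not
  pixel statistics, spatial correlations, or class overlap of real images.
* **Planted composite networks** ([make_planted_relay_network()]): one
  analytic two-hidden-node one-versus-rest detector per class — each node
  matches one half of the class prototype, the output fires on their
  conjunction — assembled by [compose_networks()] into a block-sparse
  composite, optionally with inert nodes and redundant copies. Ground truth
  is exact: class $i$'s output depends on hidden slots $(2i+1, 2i+2)$ only.
* **Exact joint tables** ([exact_relay_table()]): the discrete end of the
  pipeline generated analytically, with row weights computed by enumerating
  the generative model rather than sampling. On these tables the structural
  identities (telescoping, reduction to co-information, monotone per-size
  maxima, greedy = exhaustive) are tested at `1e-12`, free of sampling
  noise. Detector pairs come in a conjunctive (`"and"`) encoding, whose
  members are individually informative and essential, and a parity
  (`"xor"`) encoding, whose members are individually invisible — the
  synergy/redundancy edge cases discussed above.

One structural fact discovered while building the fixtures deserves
emphasis, because it constrains what "ground-truth recovery" can mean. In a
one-hot multi-class table where *every* class has its own informative
detector, the complement of class $i$'s pair is itself informative about
class $i$ (seeing that no other detector fired shifts the posterior), so
$I_R(i)$ of the planted pair given the rest is strictly below the
full-layer value, and the $\varepsilon = 0$ minimal set is not the pair —
this is a property of the measure on one-hot channels, not an estimator
artifact. Exact pair recovery is therefore asserted on isolated
one-versus-rest channels (where the complement is genuinely independent),
while the multi-class composite is validated the way the measure supports:
the planted pair dominates the essentiality ranking of its class, attains
the column maximum of aggregated relay information, and is contained in the
$\varepsilon = 0.05$ minimal set. A related subtlety: conditioning *reveals*
as well as shields, so given one member of a parity pair in $Y_0$, the other
member alone carries the full relay information — recovery fixtures
consequently use the conjunctive encoding.

## Knockouts

A hidden node is knocked out by zeroing its incoming weights, bias and
outgoing weights; since $\tanh(0) = 0$ this is bit-identical to clamping
its activation to zero mid-forward-pass, and the package asserts that
equivalence rather than assuming it. Randomized lesions (noise injection)
are deliberately not offered: a noisy node is not a disabled node. The
knockout effect $K$ of a set, for class $i$, is the drop in class-$i$
recall (an overall-accuracy variant is a flag). The knockout panel lesions
every set visited by each class's greedy trajectory and regresses $K$ on
z-scored set size and z-scored $I_R(i)$; the two predictors are also fitted
alone, and compared by the ratio of their residual variances. Z-scoring is
a package choice (the source analysis plots both coefficients on one axis
without stating a scaling); raw-unit slopes are available with
`standardize = FALSE`. One argmax artifact to know about: when all outputs
of a lesioned network are frozen, ties resolve to the lowest index, so the
fallback class can show a small *negative* knockout effect. That is a
property of deterministic tie-breaking, not a bug.

## Training

Networks are one-hidden-layer tanh/tanh with an argmax readout, trained by
mini-batch Adam on mean squared error against one-hot targets coded in
$\{-1, 1\}$ (matching the tanh output range). Training stops at the first
epoch whose accuracy reaches the target (0.98 for sub-networks, 0.96 for
full networks, matching the practical ceilings of the two architectures) or
at the epoch cap. Adam hyperparameters (learning rate `1e-3`, batch 64,
$\beta_1 = 0.9$, $\beta_2 = 0.999$) are the field's defaults and are
configurable; they are immaterial to the information analysis, which never
sees the optimizer. Fixed seeds make training bit-reproducible.

## Numerical choices and degenerate inputs

* Empty relay set: $I_R = 0$ by convention, which keeps removal traces
  telescoping ($\sum_n \Delta I(n) = I_R(\text{full})$ exactly).
* Negative $\Delta I$ from sampling noise is reported unclipped and
  flagged, never silently truncated.
* Equidistant binarization ties go to cluster 0; argmax ties to the lowest
  label; greedy ties to the lowest node index. Everything is deterministic
  given data and seed.
* Exhaustive search warns above 16 nodes and refuses above a hard cap
  (default 20), pointing to the greedy search.
* Exact-table enumeration refuses state spaces beyond $2^{16}$ rows.

## Worked example

```{r, eval = FALSE}
data <- generate_pattern_dataset(4, 16, 2000, noise = 0.02, seed = 12)
planted <- make_planted_relay_network(4, 16, n_inert = 2)
states <- record_states(planted$network, data)
table <- binarize(states, fit_binarizer(states))

report <- attribution_report(table)          # greedy search per class
minimal_set(report$traces[["1"]], 0.05)      # small set containing nodes 3, 4

panel <- build_knockout_panel(planted$network, data, report$traces)
regression_analysis(panel)                   # info beats size
```

## Problem sizes

The shipped tests and the acceptance script run the method at desk scale:
exact tables of 3–8 hidden bits (a few hundred weighted states), pattern
datasets of 400–2000 samples, composite networks of 8–14 hidden nodes, and
one 20-node table to pin the $N(N+1)/2 = 210$ evaluation count. These sizes
were chosen so the full greedy-versus-exhaustive comparison and the
20-seed recovery sweeps are exact yet complete in seconds; the method
itself scales quadratically in hidden nodes via the greedy search.

## Known limitations

* One hidden layer only; recurrent, convolutional and multi-layer
  architectures, and temporal binning of continuous recordings, are out of
  scope.
* Plug-in entropies on sampled tables are biased; the package mitigates by
  design (low-entropy class variables, exact tables for identities) rather
  than by correction.
* Single-node essentiality is blind to synergy by construction (see the
  identity above); use aggregated relay information alongside it.
* The greedy search can tie-break arbitrarily among exactly redundant
  variants; the exhaustive oracle reports all co-maximal sets so the
  ambiguity is visible rather than hidden.
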