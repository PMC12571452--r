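---
title: "Dual-branch graph neural link prediction for snoRNA-disease associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch graph neural link prediction for snoRNA-disease associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsda)
```

## The prediction problem

Validated snoRNA-disease associations form a sparse bipartite 0/1 matrix
`A` (snoRNAs in rows, diseases in columns); a 0 means *unknown*, not
*absent*. The package scores every unknown pair with a probability-like
value so that candidate associations can be prioritized. Curated collections
in this field are small (a few hundred nodes per side, on the order of a
thousand links) and have strongly skewed degree distributions: most snoRNAs
touch one or two diseases while a few hub diseases (typically common
cancers) collect a large share of all links. Every design choice below is
conditioned on that regime - full-graph training is cheap, class imbalance
is extreme, and overfitting is the dominant risk.

## Model structure

### Shared encoding and the block graph

The training graph is the symmetric block adjacency
`Y = [[0, A_train], [A_train', 0]]` with snoRNAs first (indices `1..N_S`,
diseases `N_S+1..N_S+N_D`; all downstream matrices follow this ordering).
No self-loops are added; nodes isolated by edge removal simply propagate
zeros and survive through the residual path. Raw per-side features of
arbitrary widths are mapped by one affine layer per side followed by a
rectifier into a common hidden width (`hidden_dim`, default 64), giving the
stacked matrix `F^(MLP)`. The rectifier is a conventional choice; the final
branch projections are linear so the decoder sees signed coordinates.

### Spectral branch

The spectral operator is `L_hat = -D^(-1/2) Y D^(-1/2)`, i.e. the
symmetric-normalized Laplacian shifted by the identity with its largest
eigenvalue fixed at 2 rather than computed per graph. The fixed shift is
standard spectral-GNN practice: it guarantees a spectrum inside `[-1, 1]`
for any input graph, which the Chebyshev recurrence requires, and avoids an
eigensolve per training fold. Each layer applies the polynomial filter
`sum_k w_k T_k(L_hat)` where the weights `w_k` are obtained by Chebyshev
interpolation from learnable values `gamma_j` at the nodes
`x_j = cos((j + 0.5) pi / (K + 1))`; parameterizing the filter by its values
at interpolation nodes rather than by raw coefficients suppresses the Runge
phenomenon. Two layers of orders `K = 3` and `K = 5` are the defaults. The
filter weight formula is implemented without halving the `k = 0` term; the
original-ChebNetII convention that halves it is available as
`cheb_halve_k0 = TRUE`. With all `gamma = 1` the un-halved filter is exactly
`2 I` (the halved one is `I`), which makes the all-ones initialization a
stable near-identity warm start; this closed form is also the backbone of
several tests.

### Gated branch

The gated branch runs `gated_layers = 3` layers; within a layer each node
aggregates `alpha_v = sum_{u in N(v)} Theta h_u` over the undirected graph
(edge weights fixed at 1) and a GRU cell updates the state, for
`gated_seq_len = 1` steps sharing the layer's parameters. Two printed-form
subtleties are handled explicitly:

* The aggregation uses the *neighbor* state `h_u`. The degree-scaled
  self-message variant (summing the target's own state over its
  neighborhood) contradicts the gated-graph construction the branch is
  modeled on, but is preserved behind `gated_self_message = TRUE` for
  comparison.
* The GRU is implemented exactly as the gate equations are written,
  including the two separate bias vectors per gate (an over-parameterized
  but harmless form) and the candidate state
  `eta = tanh(W_ah alpha + b_ah + beta * (W_h h + b_h))`. With all
  parameters zero each step halves the state, a property the tests exploit.

Layer inputs narrower than the state width are right-padded with zeros;
residual concatenation makes inputs *wider* than the state width, a case
the padding rule does not cover, so a learnable linear projector maps the
concatenated input down to the state width. The branch ends in its own
linear projection to `hidden_dim`, mirroring the spectral branch so both
outputs have equal width for fusion.

### Residual injection, fusion, decoding

Both branches concatenate `F^(MLP)` onto every layer input (so spectral
layer inputs run 128 then 192 columns at the default width; the first layer
concatenates `F^(MLP)` with itself). This residual mechanism is the
anti-over-smoothing device: deep propagation can only add to, never erase,
the encoded initial features. The `no-residual` ablation switches it off in
both branches. The fused embedding is `F_FINAL = [F_Cheb || F_Gated]`
(width 128) and every node pair is scored by the sigmoid inner product
`sigmoid(f_i . f_j)`; scores are clamped to `[1e-12, 1 - 1e-12]` so the
open-interval contract survives floating-point saturation. The loss is
binary cross-entropy over the snoRNA x disease block only - labels are
defined on that block, not on within-side pairs.

## Training

All parameters (encoder weights, `gamma` values, GRU matrices, projections)
are trained jointly by adaptive moment estimation (Adam) with L2 weight
decay; the optimizer is a conventional choice and its step size (5e-4) and
decay (1e-4) are the tuned defaults, as are dropout 0.01 and 600 epochs.
Each epoch scores all training positives plus an equal-size set of negatives
freshly resampled (uniformly, without replacement) from pairs that are
neither training nor held-out positives; held-out positives are excluded
from the negative pool to avoid label leakage. Resampling per epoch rather
than fixing one negative set exposes the model to the whole unknown-pair
pool while keeping each epoch balanced. Dropout (inverted, rate 0.01) is
applied to the encoder output and to every branch-layer input during
training only; the placement is a documented choice since only the rate is
prescribed. Gradients are computed by hand-written reverse-mode
differentiation through both branches (the spectral filter's adjoint is the
filter itself, since the operator polynomial is symmetric); the test suite
validates every parameter block against central finite differences on a
small instance with dropout off, the one configuration where the comparison
is exact. Weight matrices are Glorot-uniform at initialization, biases
zero, `gamma` all ones. All randomness - initialization, dropout masks,
negative draws - is taken from R's RNG seeded once per fit, so identical
seeds give bit-identical fits.

## Evaluation protocols

Ten-fold cross-validation partitions the positive pairs uniformly into
folds of near-equal size. Per fold, the evaluation set is the held-out
positives plus an equal number of negatives sampled from pairs that are not
positives anywhere (the strict reading of "unverified pairs are negative"),
and these evaluation negatives are excluded from that fold's training
negative pool. The seven metrics are AUC (rank statistic, ties counted one
half), AUPR (step summation of the precision-recall curve), and the five
confusion metrics at threshold 0.5 - a central threshold is appropriate
because the evaluation sets are balanced by construction. The report is a
tibble of per-fold rows plus mean and SD.

Two case-study protocols are provided: *novel-disease* removes every edge
of a target disease before training, so the disease is scored as an unseen
entity, and ranks all snoRNAs; *novel-association* trains on all known
positives and ranks only the target's unknown pairs. Ties are broken by
snoRNA identifier for determinism. Literature validation of ranked
candidates is manual and out of scope; the package emits the ranked table.

## The synthetic generator

Real deposits cannot be bundled, so the package ships a seeded generator
whose output exercises every pipeline stage. It plants a rank-`r` logistic
model: factors `U` (`n_s x r`) and `V` (`n_d x r`) are Gaussian with scale
`signal_strength / sqrt(r)`, association probabilities are
`logistic(c + U V')` with the intercept `c` calibrated by bisection so the
mean probability matches the target density within 1e-3, and `A` is sampled
Bernoulli. Feature matrices are the factors padded with zero columns to
`feature_dim`, plus additive Gaussian noise of sd `feature_noise` on every
entry - so with zero noise the leading feature columns are exactly the
factors, and with the default noise the planted structure is recoverable
from the features.

Default conditions are fixed once: `n_s = 200`, `n_d = 30`, `rank = 4`,
`density = 0.05`, `feature_noise = 0.1`, `feature_dim = 16`. The feature
width 16 models a modest featurizer output (signal dimensions plus nuisance
columns). `signal_strength = 2.5` is a deliberate calibration: the fixture
is validated by an oracle check requiring that ranking unknown pairs by the
true `U . V` recovers held-out positives with AUC above 0.9, and at unit
signal scale the Bernoulli sampling noise dominates the latent structure so
even that oracle ranking sits near AUC 0.66 - no method could demonstrate
recovery on such a fixture. At 2.5 the oracle AUC is about 0.96 across
seeds, leaving genuine headroom between an imperfect learner and the
ceiling. The logistic low-rank model naturally produces long-tailed disease
degrees resembling curated collections; the generator makes no attempt to
match a specific power law. What the fixture does *not* emulate: real
secondary-structure or text-embedding feature distributions, hub diseases
with hundreds of links, and curation biases - passing the recovery tests
shows the pipeline can extract a planted signal at realistic sparsity, not
that real-data performance will match.

A k-mer featurizer is included for the case where only sequences are
available: overlapping k-mer counts normalized by the window count
`len - k + 1` (so rows sum to one), `T` and `U` treated identically,
columns in lexicographic order over the RNA alphabet.

## Numerical choices and degenerate inputs

* Probabilities are clamped at `1e-12` in the loss and the decoder.
* The Chebyshev recurrence is used for both scalars and matrices; spectra
  land in `[-1, 1]` up to rounding, and eigen-oracle comparisons clip at
  the boundary.
* Isolated nodes yield zero Laplacian rows and zero messages; their
  embeddings flow entirely through the encoder/residual path.
* Duplicate association rows collapse to one with a warning (public
  deposits contain redundancy); ids are case-sensitive and kept in
  first-seen order.
* An empty training graph is permitted (the model reduces to encoder plus
  residual); an empty positive set is an error.
* Cross-validation fold seeds are derived from the user seed and reduced
  modulo `2^31 - 1` to stay in integer range.

## Problem sizes in the checks

The bundled experiments are sized for a single CPU: the recovery experiment
trains the full model and its three ablations at 300 epochs on the default
200 x 30 fixture (holding out 10% of positives, one cross-validation fold's
worth, with balanced evaluation negatives), and the acceptance script runs
the complete ten-fold protocol at the default 600 epochs on the same
fixture. Gradient and oracle checks use graphs of 4-10 nodes where
eigendecompositions and scalar re-evaluations are exact references.

## Known limitations

* On the small planted fixture the gated branch's capacity (six dense
  gate matrices per layer) lets it memorize the training edges; in the
  bundled recovery experiment the spectral-only ablation generalizes best
  and the full fusion trails it by several AUC points. This mirrors the
  overfitting risk any high-capacity branch carries at desk scale and is
  reported honestly by the tests rather than patched by re-tuning; on
  richer real features the two branches are complementary.
* Binary associations only - no association types, no confidence weights.
* No mini-batching: graphs are assumed to be hundreds, not millions, of
  nodes.
* The featurizers the model was designed around (secondary-structure and
  text-embedding features) are consumed as files; the package does not
  regenerate them.
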