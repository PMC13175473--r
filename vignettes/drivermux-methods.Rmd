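---
title: "Driver gene prioritization from multiplex directed networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver gene prioritization from multiplex directed networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivermux)
```

## The problem

Cancer driver genes (CDGs) are genes whose mutations confer a selective
growth advantage to tumor cells. Computationally, prioritizing them is a
node-classification problem with three awkward properties:

1. **Interactions are heterogeneous and directional.** Protein-protein
   contacts are undirected, but regulatory, pathway and kinase-substrate
   relations are directed; collapsing them into one undirected graph
   discards regulatory logic.
2. **Labels are scarce and one-sided.** A few hundred genes are confidently
   known drivers; there is no authoritative list of *non*-drivers, so the
   setting is positive-unlabeled (PU).
3. **Features are weakly informative per gene.** Mutation frequency,
   differential methylation and differential expression, z-scored per
   cancer type, carry signal mainly in aggregate over a gene's network
   context.

`drivermux` addresses all three: a directed graph convolution over a
*multiplex* of M networks sharing one gene set; pseudo-positive
augmentation plus one-class negative inference to build a usable training
set; and a supervised classifier with a gate-consistency regularizer.

Because no deep-learning runtime is available to R in this environment,
the package ships a small reverse-mode automatic differentiation engine
(`R/autograd.R`) operating on dense matrices with constant sparse
operators, and an AdamW optimizer. Every gradient path used by the models
is covered by finite-difference tests.

## The encoder: gated directional convolution

For layer graph $m$ with binary adjacency $A^{(m)}$ (undirected edges are
stored as arc pairs), out/in-degree matrices $D_\rightarrow, D_\leftarrow$
give the normalized operators

$$S_\rightarrow^{(m)} = D_\rightarrow^{-1/2} A^{(m)} D_\leftarrow^{-1/2},
  \qquad
  S_\leftarrow^{(m)} = D_\leftarrow^{-1/2} (A^{(m)})^\top D_\rightarrow^{-1/2},$$

with the convention $d^{-1/2} := 0$ at $d = 0$, so isolated nodes neither
send nor receive messages and no NaN can arise. For symmetric $A$ both
reduce to the classical $D^{-1/2} A D^{-1/2}$ (asserted in the tests). The
in-operator is defined as the transpose-normalization mirror: in-aggregation
reads messages along reversed arcs.

**Neighbor diversity.** Per node and direction, a Dirichlet energy measures
the feature discrepancy between a node and its in- (resp. out-)
neighborhood:

$$e = (I+S)(H \odot H) - 2\left(((I+S)H) \odot H - H \odot H\right),$$

which expands per node to
$\sum_j s_{ij} (h_i - h_j)^{\odot 2} + (1 - \sum_j s_{ij})\, h_i^{\odot 2}$.
High energy in a direction suggests class disagreement with that
neighborhood and argues for down-weighting it.

**Degree diversity.** Learnable embedding tables indexed by the raw in- or
out-degree (clamped at `max_degree`) supply a structural prior per node.
The tables are per layer, per graph and per direction: widths differ across
layers, which forces per-layer tables even though the degree itself does
not change.

**Gates.** Energies and degree embeddings are fused into scalar scores
$q_{dir} = (-e_{dir} + \mathrm{Deg}_{dir}) w_{dir} + b_{dir}$ and a
temperature softmax yields complementary directional weights
$\Gamma_\rightarrow = \sigma((q_\rightarrow - q_\leftarrow)/\tau)$,
$\Gamma_\leftarrow = 1 - \Gamma_\rightarrow$ — the two-way softmax written
in its numerically stable form, so complementarity holds to machine
precision. $w, b, \tau$ are shared across graphs within a layer; $\tau$ is
stored as a log-parameter (init 0, i.e. $\tau = 1$) so it stays positive.

**Update.** Each layer averages gated messages over the M graphs with a
residual term:

$$H^{(l+1)} = \alpha H^{(l)} + \frac{1}{M} \sum_m \left(
  \Gamma_\rightarrow^{(l,m)} S_\rightarrow^{(m)} H^{(l)} W_\rightarrow^{(l)}
  + \Gamma_\leftarrow^{(l,m)} S_\leftarrow^{(m)} H^{(l)} W_\leftarrow^{(l)}
  \right).$$

There is no elementwise nonlinearity by default — the node-level gating is
the nonlinearity; a `"relu"` switch exists (see *Numerical choices*).
Because the residual requires equal widths, the input is first lifted to
the hidden width by a learnable projection; published defaults are $L = 3$
layers of width 256, $\alpha = 0.5$, dropout 0.5 between layers (training
only).

## Pretraining: multiplex infomax with a consensus embedding

Before negative inference, an encoder of the same family is pretrained
contrastively. Each graph is encoded separately (shared weights, per-graph
degree tables) under the original features (positive view) and a
row-permuted corruption (negative view; one fresh permutation per epoch).
A per-graph bilinear discriminator scores node embeddings against the mean
readout $g^{(m)}$ of the positive view, and the per-graph loss is

$$-\tfrac{1}{n}\textstyle\sum_v \log\sigma(\tilde h_{v,+} M^{(m)} g^{(m)})
  -\tfrac{1}{n}\sum_v \log\sigma(1 - \tilde h_{v,-} M^{(m)} g^{(m)}).$$

The second term is implemented exactly as written (`1 - score` inside the
sigmoid); the conventional $\log(1 - \sigma(s))$ is available as
`negative_form = "one_minus_sigmoid"`. At zero scores the two give
$\ln 2 + \ln(1 + e^{-1}) \approx 1.0064$ and $2\ln 2$ respectively — both
frozen as test oracles.

A learnable consensus matrix $Z$ is tied to the per-graph embeddings by
$\|Z - \bar H_+\|_F^2 - \|Z - \bar H_-\|_F^2$, weighted by
$\beta = 0.001$ in the total objective. Note this term is linear in $Z$
far from the data and hence unbounded below in principle; with the small
$\beta$, AdamW's bounded steps, and the plateau-based early abort
(default: stop after 30 epochs without improvement), $Z$ stays finite in
practice and the trajectory is logged. The readout pools **all** nodes of
the positive view by default (the infomax convention); pooling only the
labeled positives is exposed via `readout_nodes` since the description
"mean pooling over the positive nodes" admits both readings.

Pretraining and classification use **separate** encoder parameter sets;
pretraining contributes only the consensus embedding $Z$ consumed by
negative inference.

## Positive augmentation

A light probability model — a Chebyshev polynomial stage
($T_0 = I$, $T_1 = \hat L$, $T_k = 2\hat L T_{k-1} - T_{k-2}$, default
$K = 2$) followed by one symmetric-normalized aggregation and a softmax —
is trained by cross-entropy on the labeled genes. The probability graph is
the symmetrized union of all layers (configurable to a single layer); the
scaled Laplacian uses $\hat L = 2L/\lambda_{max} - I$ with
$\lambda_{max}$ from 50 power iterations (deterministic start), inflated
by $10^{-6}$ so the spectrum stays inside $[-1, 1]$. Since no curated
negatives exist at this stage, the provisional negative class is an
equal-size random draw from the unlabeled pool (seeded), standard PU
practice.

Unlabeled genes whose argmax is the positive class are ranked by prediction
entropy $H_i = -\sum_c p_{ic} \log p_{ic}$ (natural log) and the
`retain_count` lowest-entropy candidates are kept (default
$2\,|S_+|$). The labeled positives are then spectrally clustered into two
clusters using an RBF affinity
$\kappa(q,u) = \exp(-\|\phi(q) - \phi(u)\|^2 / 2\sigma^2)$ on per-column
standardized features ($\phi$ fit on the positives; population SD), with
$\sigma$ defaulting to the median pairwise distance; clustering is
normalized-cut style: k-means (seeded, 10 restarts) on the row-normalized
top-2 eigenvectors of $D^{-1/2} K D^{-1/2}$. A candidate $i$ is accepted
when

$$\hat y_i = c_+,\quad p_{i,c_+} \ge \theta_p,\quad
  d_i \le \mathrm{mean}\{d\}_{S_+} + \mathrm{std}\{d\}_{S_+},$$

with $\theta_p = 0.8$ by default, $d_i$ the distance to the nearest
positive-cluster centroid, and both boundaries inclusive; std is the
population SD. The distance clause can only shrink the candidate set
(property-tested). Augmentation is single-shot — no self-training rounds.

## Negative inference

One-class *internal contrastive learning* is trained on the (augmented)
positives only. Each representation vector of length $f$ is decomposed
into all $m = f - k + 1$ contiguous windows $a_j$ of length $k$ (default
8) and their order-preserving complements $b_j$; two-layer MLP encoders
$G$ (windows) and $F$ (complements) with unit-normalized outputs are
trained so that each complement identifies its own window among the $m$
candidates:

$$\ell_j = -\ln \frac{\exp(F^N(b_j)\cdot G^N(a_j)/\tau)}
  {\sum_{j'} \exp(F^N(b_j)\cdot G^N(a_{j'})/\tau)}, \qquad \tau = 0.1.$$

The anomaly score of a gene is $y(x) = \sum_j \ell_j$; genes whose internal
feature structure the positive-trained model cannot reconstruct score high
and are taken as likely negatives. The top-scored unlabeled genes (ties
broken by ascending gene index), in a quantity equal to the number of
positives after augmentation, form the inferred negative set. By default
the ICL operates on the consensus embedding $Z$; raw features are a config
switch kept mainly for unit tests. Encoder widths (64 hidden, 32 out),
$k$, $\tau$ and the 100-epoch default are package choices, config-exposed.

## Supervised stage

A second encoder plus a linear softmax head produces per-gene driver
probabilities. The loss is the *sum* (not mean) of cross-entropies over
labeled nodes, plus $\lambda$ (default $3 \times 10^{-4}$) times a
consistency regularizer: with per-node gates first averaged over all
layers and graphs of the classifier encoder, the regularizer is the mean
squared deviation of these averages from their grand mean, summed over
both directions — algebraically the population variance of the averaged
out-gates plus that of the in-gates, and by complementarity twice the
out-gate variance (both identities are test oracles). Training uses AdamW
(lr 0.01, weight decay 0.0 by default) with early stopping on the loss of
a stratified 10% validation split of the labeled nodes (patience 30,
max 1000 epochs); the best-validation parameters are restored.

## Evaluation harness

`metrics()` computes rank-based AUROC with midrank ties (verified against
exhaustive pair enumeration), AUPRC as step-integrated average precision,
and F1 at threshold 0.5. `cross_validate()` runs repeated stratified
k-fold CV over the labeled genes (the published protocol is ten runs of
five-fold CV). To avoid label leakage, pseudo-positive augmentation and
negative inference are **re-run inside each training fold** using only
that fold's training labels; a `global_mode` flag performs one-shot global
augmentation instead, for comparison. `imbalance_experiment()` re-runs CV
at positive:negative ratios such as 1:1, 1:1.5, 1:2 by truncating a ranked
negative pool. `cdg_interaction_analysis()` counts, per gene and layer,
known-driver in-, out- and unique total neighbors (a driver seen in both
directions counts once; for undirected layers the three counts coincide)
and reports Spearman correlations between gene scores and counts with
large-sample t p-values.

## The synthetic world

`generate_synthetic()` states the test world once:

* **Topology.** Planted-partition layers: within-class ordered pairs get
  edge probability proportional to homophily $h$, cross-class pairs to
  $1-h$, rescaled so the expected density is met exactly. Default M = 6
  layers, 3 directed — the mix of the real network panel (PPI, complexes,
  pathway, regulatory, gene-association, kinase-substrate).
* **Direction.** In directed layers, cross-class arcs are scaled by
  $1+\delta$ in the driver $\to$ non-driver orientation and $1-\delta$ in
  the reverse. This preserves the expected density and — at $h = 0.5$ —
  leaves the symmetrized graph with *no* class signal at all (degree and
  neighbor composition become class-identical in expectation), while the
  directed graph retains strongly class-dependent in/out-degree profiles.
  That makes $h = 0.5$ the cleanest setting for isolating directionality.
* **Features.** Class-conditional Gaussians: a fraction (default 25%) of
  columns is shifted by `effect` SDs for drivers, then columns are
  z-scored. The pipeline consumes only z-scored continuous features, so a
  Gaussian shift is the minimal sufficient emulation; no attempt is made
  to mimic real degree distributions, omics marginals or feature
  correlations — a green test establishes correctness of the machinery and
  recoverability of planted signal, not real-data performance.
* **PU structure.** A `hidden_frac` (default 20%) of true positives is
  relabeled unlabeled, so augmentation recovery is measurable against
  ground truth.

Presets: `easy` ($h=0.9$, effect 2), `medium` ($h=0.7$, effect 1),
`hard` ($h=0.5$, effect 0, $\delta=0$ — a pure null).

## Numerical choices and desk-scale experiment design

* Gates via $\sigma(\Delta q / \tau)$ (max-subtraction equivalent);
  log-sigmoids and log-softmaxes in stabilized forms throughout.
* Zero-degree inverse square roots are defined as 0.
* Constant feature columns z-score to zeros, not NaN.
* Anomaly-score ties break by ascending gene index; k-means uses 10
  seeded restarts.
* The encoder's optional `"relu"` switch (default off) matters at desk
  scale: with mean-zero z-scored features and no nonlinearity, messages
  are mean-zero and per-node gate/degree signals have no carrier into the
  representations. With ReLU, hidden activations acquire a positive mean
  and second-layer aggregates scale with $\sqrt{\text{degree}}$, making
  directional degree structure linearly readable. The directionality
  experiments therefore enable ReLU in *both* arms.
* At n ≈ 200 with ~100 labels, the published defaults (weight decay 0,
  degree clamp 512) let the degree tables memorize training nodes within
  a few epochs. The bundled experiments use weight decay 5e-4 and
  `max_degree` 64; package defaults keep the published values.
* The directionality comparison is run at $h = 0.5$, effect 0.75,
  $\delta = 0.5$ (see *The synthetic world*) rather than the easy preset,
  where both arms saturate near AUROC 1 and a paired comparison has no
  power. Augmentation stages are disabled in both arms of that comparison
  to isolate the directionality factor; augmentation recovery is tested
  separately.
* The imbalance trend on the easy preset sits at the AUPRC ceiling
  (medians tie at 1 across ratios); the non-increasing check passes but is
  weak evidence there — the informative observations are the augmentation
  and directionality experiments.

## Known limitations

* Pure-R training: fine for $n \lesssim 10^3$ nodes and hidden widths
  $\lesssim 64$; the published scale ($n \approx 10^4$, hidden 256) would
  need hours, not seconds.
* The consensus loss is unbounded below in $Z$ as printed; mitigations
  above.
* Five-fold CV is over labeled genes only; unlabeled genes receive scores
  from every fold model but are never test items.
* No attention-based cross-network fusion: layers are averaged with equal
  weights.
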