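---
title: "Drug-to-drug network features for ADR prediction: methods and design notes"
author: "adrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-to-drug network features for ADR prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrnet)
```

# The model

`adrnet` predicts adverse drug reactions (ADRs) per label: each ADR with
enough associated drugs becomes a binary classification target over all
drugs. The distinguishing step is a *drug-to-drug network* built from the
incidence matrix itself.

## Bipartite projection

The binary drug × ADR incidence matrix defines a bipartite graph (drugs on
one side, ADRs on the other, an unweighted edge per known association; the
source data carry no reliability score, so association edges cannot be
weighted). Projecting onto drugs joins two drugs whenever they share at
least one ADR, with raw edge weight

$$w(u, v) = \sum_a M_{ua} M_{va},$$

the shared-ADR count. The biological reading: drugs causing the same
reactions plausibly act on the same proteins via the same pathways, and
the more reactions they share the stronger that latent link. Raw weights
are min-max normalised, $w' = (w - w_{\min})/(w_{\max} - w_{\min})$, so
that heavy edges cannot drown the drug features downstream.

*Degenerate case.* When every edge has the same raw weight the formula is
0/0. We define all normalised weights as 1, preserving the network; the
alternative (all 0) would silently delete every edge from the two
weight-aware features.

## The ten node features

| letter | feature | weights used | definition |
|---|---|---|---|
| D | degree centrality | no | $\deg(v)/(N-1)$ |
| W | weighted degree (strength) | yes | $\sum_{u \in nbr(v)} w'(u,v)$ |
| E | eigenvector centrality | no | principal eigenvector of the adjacency, unit $L_2$ norm |
| O | closeness | no | $(N-1)/\sum_u d(v,u)$, unweighted shortest paths |
| C | clustering coefficient | no | $2T(v)/(\deg(v)(\deg(v)-1))$, 0 when $\deg < 2$ |
| B | betweenness | no | Brandes accumulation, normalised by $2/((N-1)(N-2))$, endpoints excluded |
| A | authority (HITS) | no | see below |
| H | hub (HITS) | no | see below |
| T | triangles | no | triangles through $v$ |
| P | weighted PageRank | yes | stationary weighted random walk, damping 0.85 |

Exactly two features — W and P — consume the normalised weights; the other
eight see edge existence only. This split is load-bearing: permuting the
edge weights while holding topology fixed must change only the W and P
columns (this is asserted bit-for-bit in the tests and the acceptance
script), so any advantage those two features show over the rest isolates
the information carried by the *weights*.

Weighted PageRank treats the undirected edges as bidirectional: a walker
at drug $u$ moves to neighbour $v$ with probability
$w'(u,v)/s(u)$, $s(u) = \sum_x w'(u,x)$, giving

$$PR(v) = \frac{1-d}{N} + d \sum_{u \in nbr(v)} PR(u)\,\frac{w'(u,v)}{s(u)}, \qquad d = 0.85.$$

Nodes with zero strength (isolated, or all incident weights normalised to
0 — which happens to every minimum-weight-only node) are treated as
dangling and redistribute uniformly. Scores sum to 1.

### Numerical choices

- **Spectral shift.** Eigenvector centrality is computed by power
  iteration on $A + I$ rather than $A$. On (near-)bipartite graphs the
  adjacency spectrum contains $\pm\lambda_1$ and plain iteration
  oscillates; the shift maps the spectrum to $\lambda + 1 \ge 0$ and
  converges to the same Perron vector for every connected graph.
- **HITS on an undirected graph.** With edges treated as reciprocal
  directed pairs, the mutual-reinforcement recursion
  $a = A^\top h,\ h = A a$ collapses: hub and authority share the
  non-negative principal eigenvector of the symmetric adjacency, which
  also spans the leading eigenspace of $A^\top A$. We compute it with the
  same shifted power iteration, so hub = authority holds exactly (and is
  asserted). Iterating the pair naively instead is not well-defined on
  bipartite graphs, where the leading eigenspace of $A^2$ is degenerate.
  A consequence worth knowing: on any undirected network E, A and H are
  numerically the same column.
- **Convergence.** Power-iteration measures use max-norm tolerance
  1e-10 (PageRank 1e-8) and an iteration cap of 1000, erroring with the
  iteration count on failure rather than returning a stale iterate.
- **Disconnected graphs.** The projected network of a real incidence
  matrix is typically near-complete, but the code does not assume it:
  closeness falls back to the Wasserman–Faust within-component form
  $\frac{r-1}{\sum d} \cdot \frac{r-1}{N-1}$ ($r$ = reachable nodes);
  eigenvector/HITS are computed on the largest component with zeros
  elsewhere and the output flagged; summary path statistics are computed
  on the largest component and flagged.
- **Betweenness tie handling** is exact: Brandes propagates shortest-path
  counts, so equal-length paths share dependency; no sampling is used.

## Dimensionality reduction and rebalancing

The one-hot drug features (six binary blocks: chemical, enzyme,
indication, pathway, target, transporter) are concatenated — at full
pharmacological scale 881 + 111 + 869 + 173 + 786 + 72 = 2892 columns —
and reduced by PCA to 10 components (mean-centred SVD; at full scale ten
components explain roughly half the variance, and
`componentsForVariance()` supports choosing a count for any target). PCA
is fitted once on all drugs before cross-validation, reproducing the
original experimental procedure; this leaks no labels (features only) but
does use test-fold feature rows, and a per-fold variant can be obtained by
fitting inside a resampling loop if wanted.

Class imbalance is addressed by SMOTE, applied inside each training fold
only, and only when the fold's positive/negative ratio falls below the
trigger 0.4. The minority class is topped up to
$\lfloor 0.43 \cdot n_{\text{majority}} \rfloor$ points; each synthetic
point is $x + u (x_{nbr} - x)$, $u \sim U(0,1)$, with $x_{nbr}$ one of the
$k = 5$ nearest minority neighbours (Euclidean; ties broken by lowest row
index; $k$ capped at $n_{\text{minority}} - 1$). Synthetic rows are
tagged and never reach a test fold. The count convention
$\lfloor r \cdot n_{maj} \rfloor - n_{min}$ reproduces the canonical
61-positive / 771-negative example: $\lfloor 331.53 \rfloor - 61 = 270$
synthetic points.

## Evaluation

For each eligible ADR (≥ 15 associated drugs, so a 10-fold split can put a
positive in most test folds), each feature set of the cumulative ladder
(baseline, +D, +DW, …, +all ten) and each requested classifier, we run
seeded shuffled (non-stratified) 10-fold cross-validation; a `stratified`
flag exists. AUROC is computed as the Mann–Whitney rank statistic (ties
count one half, exactly the trapezoidal ROC area); test folds containing a
single class contribute no AUROC and are flagged. Accuracy thresholds
scores at 0.5 — an explicit choice, since an operating point has to be
fixed somewhere. The network is built once from the full incidence matrix,
*including* each target ADR's own column, faithfully reproducing the
original design; this is an inherent optimistic bias of that design, and
`holdoutAdrEdges = TRUE` rebuilds the network without the target ADR for
the leakage-free variant.

Classifiers: logistic regression (`glm`), decision tree (`rpart`
defaults), XGBoost (small fixed grid, depth {3, 6} × learning rate
{0.1, 0.3}, tuned on a held-out quarter of each training fold), random
forest (`ranger`, probability forest, `max.depth = 10` — chosen over
`randomForest`, which exposes no depth control), SVM (`e1071`, probability
scores), kNN (`class::knn`, k = 5, neighbour-vote scores), and a
single-hidden-layer neural network (`nnet`, width 32, BFGS optimiser —
the R analogue of a one-hidden-layer Keras/Adam model; the optimiser
differs, the model class does not).

## Feature importance

Per ADR, a logistic regression of the label on the full 20-column feature
set (10 PCs + 10 network features) yields a two-sided Wald p-value per
feature; means and standard deviations across ADRs summarise which
features matter.

**Why Firth.** On a near-complete network, eight of the ten centrality
columns are nearly constant across drugs, and with strong signal at a few
hundred drugs the classes are frequently linearly separable in 20
dimensions. Under separation the unpenalised maximum-likelihood estimate
diverges and its Wald statistic collapses; in trial runs *every* eligible
ADR of the default synthetic dataset was affected, which would empty the
importance aggregate entirely. The default fit is therefore Firth's
bias-reduced logistic regression (Jeffreys-prior penalty), which keeps
estimates finite and Wald-type tests usable under separation while
changing well-behaved fits only negligibly; `method = "wald"` provides the
classic unpenalised fit with a separation flag for comparison. Columns are
standardised before fitting (a coefficient's Wald p-value is invariant to
rescaling its column), columns beyond the numerical rank of the design are
dropped via pivoted QR and inherit the p-value of a retained column they
are numerically identical to (hub, authority and eigenvector coincide on
an undirected network; either convention — NA or inheritance — is
defensible, and inheritance keeps the ten-feature summary total), and
constant columns get `NA`. Non-converged fits are flagged and excluded
from aggregates.

The SMOTE placement for this analysis is ambiguous in the original
procedure (inside folds vs once per ADR); we apply it once per ADR on the
full set for the p-value fit — there is no test fold to protect in a
pure inference step — and per fold for AUROC.

# The synthetic-data generator

`simulateAdrData()` emulates the *dependency structure* the analysis
exploits, not real pharmacology. A configurable number of latent
mechanisms (think: a protein/pathway a drug acts on) each governs a random
subset of ADRs and of feature columns (each pair governed with probability
0.1). Drugs carry mechanisms with Zipf-like popularity
($p_m \propto m^{-1.5}$, scaled to 2 mechanisms per drug on average, at
least one each): a few mechanisms are common, most are rare, which
reproduces the right-skewed ADR frequency distribution (many ADRs backed
by very few drugs) that motivates the eligibility filter and SMOTE. A drug
shows an ADR governed by one of its mechanisms with probability 0.8
(`linkStrength`) and any other ADR with probability 0.02 (`adrBaseRate`);
feature bits governed by its mechanisms are set and every bit is then
flipped with probability `featureNoise`.

Defaults are a one-tenth-scale analogue of an 832-drug / 1385-ADR / six
feature block dataset: 200 drugs, 150 ADRs, block widths
(88, 11, 87, 17, 79, 7), 25 mechanisms. The default `featureNoise = 0.5`
makes the feature bits *pure noise*: this is the deliberate stress
condition under which the baseline must sit at chance and every bit of
predictive lift must travel through the network features, so the
evaluation isolates exactly the contribution the method claims.

What the generator does **not** emulate: drug chemistry or dosage, ADR
category hierarchies, reporting biases, or any claim about the real
generative process of pharmacovigilance data. Passing tests on synthetic
data show the pipeline recovers a planted shared-mechanism signal; they do
not certify performance on real incidence matrices. The ground-truth
latent assignment is written for diagnostics but never read by any
pipeline stage, so it cannot leak.

# Problem sizes and determinism

Tests and the acceptance script run at the scales a laptop handles in
minutes: the default 200 × 150 synthetic dataset for the end-to-end
evaluation (LR, baseline vs full ladder, ~80 eligible ADRs), 50 random
graphs of up to 30 nodes for the centrality oracle sweep, and the printed
worked examples for the exact checks. Every stochastic step — generator,
fold shuffling, SMOTE interpolation, stochastic classifiers — is seeded,
and the generator is bitwise reproducible for a fixed configuration across
processes; RNG state is always restored, so library calls never perturb
the caller's random stream.

# Known limitations

- Hub, authority and eigenvector centrality are numerically one feature
  on undirected networks; they are kept as three columns for fidelity to
  the ten-feature inventory, and the importance analysis handles the
  collinearity explicitly.
- The near-complete regime (density → 1) makes most topology-only
  features nearly constant; discriminative power then rests almost
  entirely on W and P. This matches the motivating observation but means
  the ladder's middle rungs add little on dense networks.
- AUROC means average over ADRs with equal weight regardless of
  frequency; rare-but-eligible ADRs contribute as much as common ones.
- The full-incidence network reuses the target ADR's associations
  (original design); treat reported AUROCs as measuring the design as
  published, and use `holdoutAdrEdges` for deployment-style estimates.
- Betweenness is exact Brandes, $O(NE)$; fine to a few thousand drugs,
  not tuned beyond that.
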