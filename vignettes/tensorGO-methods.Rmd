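---
title: "tensorGO: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tensorGO: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and its
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, the numerical choices, and the design decisions taken
where the design was genuinely open.

## The prediction problem

Automatic protein function prediction assigns Gene Ontology (GO) terms to
proteins. Three properties shape the method:

1. **Multi-view inputs.** Proteins are described by several heterogeneous
   feature sets ("views"): dense sequence embeddings from a protein language
   model, sparse binary InterPro domain/family fingerprints, and
   protein–protein interaction (PPI) profiles. Views carry complementary
   signal and have different dimensions.
2. **Multi-label, hierarchical outputs.** A protein carries many GO terms at
   once, and the GO is a DAG under the true-path rule: annotation to a term
   implies annotation to every ancestor. Predictions must respect this.
3. **Severe class imbalance and homology leakage.** Most terms are rare, and
   naive random splits leak sequence homology from train to test.

## The model

For views $x^{(d)} \in \mathbb{R}^{n_{x_d}}$, $d = 1,\dots,n_d$, a degree
$n_d$ polynomial over pure cross-view monomials has weight tensor
$T \in \mathbb{R}^{n_{x_1} \times \dots \times n_{x_{n_d}}}$. tensorGO
stores $T$ in CP (canonical polyadic) form with rank $n_t$,
$T = \sum_t \lambda_t \bigotimes_d p_t^{(d)}$, and factorizes each view's
factor matrix a second time, $P^{(d)} = V^{(d)} U^{(d)\top} D^{(d)}$:
per-feature directions (rows of $U^{(d)}$, unit norm), per-feature scales
(the diagonal $D^{(d)}$), and per-component mixing (rows of $V^{(d)}$, unit
norm). The multi-label output is produced by a projection
$Q \in \mathbb{R}^{n_y \times n_t}$ with unit-norm columns, and optional
ReLU activations $\mathcal{A}$ (inside, after $U^{(d)\top}D^{(d)}x$) and
$\mathcal{B}$ (outside, after $V^{(d)}$) make the map non-polynomial:

$$\hat y(x) = Q\,\bigl(\lambda \circ {\textstyle\prod_d}
  \mathcal{B}\bigl(V^{(d)} \mathcal{A}(U^{(d)\top} D^{(d)} x^{(d)})\bigr)\bigr).$$

The activation order is fixed by the model definition: $\mathcal{B}$ is
applied inside the cross-view product, the core weights $\lambda$ outside.
Training minimizes the regularized mean squared error
$\tfrac{1}{2mn_y}\lVert Y - \hat Y\rVert_F^2 +
\tfrac{C_\lambda}{2n_t}\lVert\lambda\rVert^2$ subject to the unit-norm
constraints.

**Assumptions.** Squared error treats the binary labels as regression
targets; scores are therefore clipped to $[0,1]$ before thresholding (a
documented flag disables clipping for real-valued targets). The pure
product structure assumes the useful signal lives in cross-view
interactions; see "intercept augmentation" below for how lower-order terms
are recovered.

### Why an explicit tensor oracle exists

With identity activations the model *is* a CP-factorized polynomial.
`explicitWeightTensor()` materializes $T$ (guarded to $10^6$ entries) and
`polynomialCoefficient()` computes single coefficients
$w_{j_1\dots j_{n_d}} = \sum_t \lambda_t p^{(1)}_{j_1 t}\cdots
p^{(n_d)}_{j_{n_d} t}$. The test suite contracts $T$ against random inputs
with nested loops and checks the factorized forward map against it to
$10^{-8}$ — the strongest correctness anchor in the package, because it
validates the entire forward computation path against first principles.

## Training: gradients, constraints, optimizer

Gradients of the forward map are derived analytically (chain rule through
scale → $U$ → $\mathcal{A}$ → $V$ → $\mathcal{B}$ → product → $\lambda$ →
$Q$) and implemented with dense matrix algebra; no autograd framework is
used. Any implementation reproducing the same objective decrease is
conforming, and the analytic path keeps the package dependency-free.

Constraints are enforced by projection: after every mini-batch step, rows
of each $U^{(d)}$ and $V^{(d)}$ and columns of $Q$ are rescaled to unit
norm (zero rows are replaced by a seeded random unit vector and the event
logged). Projection is idempotent and the post-epoch residual is recorded
in the training report; the suite asserts it stays below $10^{-6}$.

Defaults: Adam, step size $10^{-3}$, batch 128, $C_\lambda = 0$ — declared
package defaults, not claims about any reference configuration. The
per-view inner dimension $k_d$ defaults to $\min(n_t, n_{x_d})$. $\lambda$
is unconstrained in sign and initialized small positive; per-feature scales
start at $1/\sqrt{n_{x_d}}$ so activations are $O(1)$ for standardized
features. When validation proteins are supplied, the epoch with the lowest
validation objective supplies the returned model.

### Intercept augmentation

A pure cross-view product model cannot represent per-term intercepts or
per-view linear effects — with binary labels it cannot even express a
term's base rate, which is exactly what the Naive baseline exploits.
`addInterceptFeature()` appends a constant unit coordinate to every view,
the standard factorization-machine device; the product form then reproduces
all lower-degree polynomial terms exactly, while the core model code is
unchanged. `runTrain()`/`runPredict()` apply it by default and record the
choice in the model archive. In our synthetic studies this is the
difference between losing to and clearly beating the frequency baseline.

## The label pipeline

* **OBO parsing** honors `id`, `alt_id`, `name`, `namespace`, `is_a` and
  `is_obsolete` only; `relationship:` lines (part_of, regulates, …) and
  `[Typedef]` stanzas are ignored because the label semantics here are
  is-a-only. Obsolete terms are dropped; each namespace must have exactly
  one parent-less root. Cycles and dangling references are structural
  errors naming the offending edge or id.
* **True-path propagation** replaces each protein's term set with its
  ancestor closure (self included, up to the namespace root); it is
  idempotent and monotone, and alternate-id mappings are counted in logs.
* **Label-space selection** keeps namespace terms annotated in at least
  `minCount` proteins (conventionally 30 for MFO/CCO, 60 for BPO),
  excludes the namespace root, and orders terms topologically with
  lexicographic tie-break so label matrices are reproducible run to run.
  Ancestor bookkeeping inside the space is transitively closed and
  1-based.
* **Information content** is conditional:
  $I(v) = -\log_2\bigl(n(v)/n(\mathrm{Pa}(v))\bigr)$ bits, where the
  multi-parent denominator counts proteins annotated with *all* parents
  jointly — on propagated data $v$ implies all its parents, so
  $I(v) \ge 0$ with no smoothing needed (the selection threshold guarantees
  positive counts). A term co-extensive with its parents carries 0 bits.
* **Score propagation** post-processes predictions so every in-space
  ancestor's score is the maximum over itself and its in-space
  descendants; the result satisfies parent ≥ child on every in-space edge,
  never decreases an entry, and is idempotent. Propagation stops at the
  in-space frontier because roots are excluded from evaluation.

## Evaluation conventions

Protein-centric CAFA metrics over the threshold grid
$\tau = 0.01, 0.02, \dots, 1.00$ (the package default; any strictly
increasing grid in $(0,1]$ can be supplied):

* precision at $\tau$ averages TP/predicted over the $m(\tau)$ proteins
  with at least one call; thresholds with $m(\tau) = 0$ are skipped;
* recall averages TP/true over *all* test proteins; proteins with empty
  true sets contribute recall 1 (and 0 to remaining uncertainty) — such
  proteins can arise on filtered label spaces;
* weighted variants replace counts with IC-weighted masses; with uniform
  IC they reduce to the unweighted metrics exactly;
* Smin: $ru(\tau)$/$mi(\tau)$ are the mean total IC of false negatives /
  false positives per protein (the prose semantics: misinformation = IC of
  false positives), and $S_{\min} = \min_\tau \sqrt{ru^2 + mi^2}$;
* AUPRC is the threshold step sum taken in decreasing-$\tau$ order,
  anchored at recall 0, absolute value reported — grid-resolution limited
  by construction, and perfect predictions score 1;
* AUROC is micro-averaged over pooled protein–term pairs via the
  ties-averaged rank statistic, which equals the probability that a random
  positive outscores a random negative with ties counted ½ — the quantity
  the threshold-sum formulation estimates;
* coverage is the fraction of proteins with any strictly positive score.

Optimal thresholds report the smallest argmax (argmin for Smin), making
reports deterministic under ties.

## Cross-validation

Sequence clusters (e.g. from 30%-identity clustering) — not proteins — are
shuffled with the seed and dealt round-robin into `nFolds` groups; fold *i*
tests on group *i*. The validation carve-out is also cluster-wise: whole
clusters are drawn from the training side until at least `valFraction`
(default 10%) of training proteins are covered. No cluster ever spans the
train+validation side and the test side, so test proteins share no cluster
with anything the model or its selection saw. `runTrain()` follows the
validate-then-refit protocol: model selection on the validation clusters,
then a refit on train+validation before test prediction (disable with
`refit = FALSE`).

## The synthetic generator

`simControl()` defaults define the reference desk-scale study: m = 1000
proteins, two Gaussian views of 20 dimensions, a planted rank-4 model, a
depth-3/branching-3 single-root DAG (39 non-root terms, a fraction with two
parents), per-term positives above the 0.8 score quantile, 5% label noise,
80 clusters. Choices and rationale:

* labels are generated by thresholding *max-propagated*, per-term min-max
  scaled truth scores and then re-closing under ancestors, so Y satisfies
  the true-path rule by construction (real data gets this from curation);
* per-term (not global) scaling guarantees every term has positives at
  quantile thresholds below 1; degenerate constant-score terms become
  all-zero columns and are logged;
* noise flips positive frontier terms off and negative terms on, followed
  by upward re-closure, preserving consistency — 5% is a realistic
  annotation error rate for experimentally supported records;
* 80 clusters of 1000 proteins give a median cluster size near the small
  multi-member clusters produced by 30%-identity clustering, while leaving
  enough clusters for 10 folds.

What the generator does **not** emulate: realistic sequences or embedding
geometry (views are i.i.d., so there is no homology structure for the
cluster split to exploit — split hygiene is still audited, but its benefit
cannot be measured here), evidence-code biases, term depth/frequency
distributions of the real GO, or inter-protein correlation. Passing tests
therefore demonstrate correctness of the machinery and the qualitative
model-vs-baseline ordering, not real-data effect sizes.

## Problem sizes and numerical choices

The suite and the acceptance script run, on one CPU, with: 100 random
models (dims ≤ 5 per view, rank ≤ 4) for the tensor oracle; a planted
2-view recovery at dims 20/20, rank 3, m = 2000 train / 500 held out, 300
epochs of Adam at step $10^{-2}$; metric oracles on 50 fixtures of at most
10 proteins × 8 terms; 100 random ontologies for the consistency audit; and
one full synthetic study (m = 1000, rank-12 fit, 200 epochs at step
$3\times10^{-3}$, $C_\lambda = 10^{-4}$) for the baseline comparison. These
sizes were chosen as the smallest at which each property is
unambiguous.

Other numerics: unit-norm feasibility tolerance $10^{-6}$ (post-projection
residuals are at machine precision); divergence (non-finite objective)
aborts with the last finite objectives in the message; prediction TSVs
round half-even to 3 decimals and omit zeros (evaluation reconstructs
them); all random draws flow through explicit seeds and restore the
caller's RNG state.

## Known limitations

* The trainer is plain R matrix algebra: fine at desk scale and for
  reduced views (~1000 dims), but a compiled or GPU path would be needed
  for full fingerprint matrices at corpus scale.
* Squared-error training of binary labels is calibrated only through the
  clip-and-threshold convention; a cross-entropy objective is a natural
  extension and would change the optimal-threshold behavior.
* Information content is estimated from the dataset itself; on small
  synthetic studies rare terms get noisy IC, which propagates into WFmax
  and Smin.
* The CP rank $n_t$, $C_\lambda$, epochs and step size are free
  hyperparameters; package defaults are starting points, and the
  validation carve-out exists precisely to select among them.
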