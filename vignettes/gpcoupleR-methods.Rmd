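---
title: "Predicting GPCR-transducer coupling from language-model embeddings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting GPCR-transducer coupling from language-model embeddings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

G protein-coupled receptors (GPCRs) signal by coupling to intracellular
transducers: the four heterotrimeric G protein families (G~s~, G~i/o~,
G~q/11~, G~12/13~, seventeen transducer genes plus the β-arrestins in the
default vocabulary) with selectivity profiles ranging from exclusive to
promiscuous. Quantitative binding screens measure continuous activities for
receptor-transducer pairs, but coverage of the receptorome is incomplete.
gpcoupleR implements a prediction-and-interpretation pipeline that treats
per-layer, mean-pooled transformer protein-language-model embeddings as
receptor features and learns one binary coupling classifier per transducer.

The package deliberately separates the *embedding provider* (an external
neural network; here a contract plus a deterministic synthetic stand-in)
from everything downstream, so the statistical machinery is fully testable
offline.

## Labels: assay-specific binarization

Each coupling table carries continuous activities from one of three
sources, binarized with strict thresholds:

| assay | quantity | coupled iff |
|-------|-----------|-------------|
| TGF   | log10 relative intrinsic activity (logRAi) | value > −1 |
| GEMTA | double-normalized Emax | value > 0 |
| UCM   | relative activity | value > 0 |

Boundary values are non-coupled; missing cells are excluded from training
rather than imputed (no imputation rule is defensible for these assays, and
class balance is handled by balanced class weights instead). Binarization
is monotone in the activity by construction.

## Features: per-layer PCA at 95% variance

Embeddings are 1280-dimensional mean-pooled vectors per receptor and layer
(the backbone exposes 34 residue-representation layers, indexed 0–33; with
two algorithm families this yields the 68 candidate models per transducer
that `enumerate_candidates()` returns). Each layer's matrix is reduced by
mean-centered PCA keeping the smallest K components whose cumulative
explained-variance ratio reaches 0.95. Two numerical conventions make
results reproducible across platforms:

* component signs are fixed so each loading row's largest-magnitude entry
  is positive (PCA signs are otherwise arbitrary);
* held-out receptors, variants and space queries are always projected with
  the *stored* center and loadings — the PCA is fit once on the training
  assay's receptors and never refit, avoiding leakage.

## Model selection protocol

For each transducer and candidate (layer, algorithm), `cross_validate()`
runs stratified 5-fold cross-validation repeated 10 times with fresh fold
draws (fold seeds are `seed + repeat`). The declared hyperparameter spaces
are: logistic regression with penalties {l1, l2}, the five named solvers
with incompatible (penalty, solver) pairs skipped, C ∈ [0.001, 100],
max_iter 4000; SVC with kernels {linear, poly degree 3, rbf, sigmoid},
gamma = "scale", C ∈ [0.1, 100]; class weights balanced throughout. Two
choices deserve explanation:

* **C grid.** The protocol names only an interval for the inverse
  regularization strength, so the grid realizes it as 7 log-spaced points,
  endpoints inclusive (`c_grid()`), overridable per call.
* **Solvers.** A solver determines how the optimum is found, not which
  model is fitted, so the solver axis exists in the declared space
  (`logreg_space()`) but the fitted search runs over (penalty, C), with
  glmnet as the penalized-likelihood solver (`lambda = 1/(C·n)` maps the
  C convention onto glmnet's).
* **Grid search × repeats.** How a grid search should interact with
  repetitions is genuinely open. Selecting a winner *within* each repeat
  and averaging the winners' scores inflates null performance by roughly
  the expectation of a maximum (we measured chance-level AUC near 0.6 on
  signal-free features under that scheme). gpcoupleR therefore runs one
  search scored across all repeats' folds: every grid point is evaluated
  on every fold, the best overall mean AUC wins, and the reported metrics
  are that single point's per-repeat averages. Label-shuffle nulls then
  sit at AUC ≈ 0.5, as a randomization test should.

Candidates whose |REC − SPE| exceeds 0.15 are eliminated (the exact 0.15
boundary survives; an epsilon guards float representation), survivors are
ranked by mean AUC (ties: higher MCC, then lower layer), the top 5 proceed
to held-out evaluation. Because literature-derived test sets carry no true
negatives, held-out performance is recall at the 0.5 probability
threshold, with a hard leakage guard rejecting any overlap with training
receptors. The final per-transducer model maximizes test recall (ties:
higher CV AUC).

AUC is rank-based on continuous decision scores, so SVC needs no
probabilities during selection; predicted coupling probabilities for SVC
use Platt-style calibration as fitted by e1071, while logistic models use
their native probabilities.

## Attention-head importance

The pooled representation concatenates 20 attention heads × 64 dimensions.
For a linear classifier on PCA scores, the weight mass can be backprojected
onto original dimensions: normalize classifier weights to
$\bar w^{cl}_k = |w^{cl}_k| / \sum_k |w^{cl}_k|$ (intercept excluded — the
sum runs over the K component weights only), normalize each loading row to
$\bar w^{PCA}_{j,k} = |w^{PCA}_{j,k}| / \sum_j |w^{PCA}_{j,k}|$, and sum
the reweighted matrix $\bar w^{cl}_k \bar w^{PCA}_{j,k}$ over each head's
contiguous 64-column block. Head h owns columns $(h-1)\cdot 64 + 1$ through
$h \cdot 64$ — the only tiling consistent with a 1280-wide matrix and 20
heads. The importances are non-negative and sum to exactly 1 (each
normalization sums to 1, so the double sum telescopes); the most important
head is the argmax, ties resolving to the lowest index. Non-linear SVC
models carry no usable weight vector, so interpretation falls back to the
logistic model trained on the same layer and assay.

## Differential contact enrichment

Predicted intramolecular contact maps (probabilities, from the external
backend) are binarized at a strict 0.5. Positions in loops and termini are
aggregated to their segment label *before* pairing (duplicate pairs
collapse per receptor); helical positions (TM1–TM7, H8) keep their generic
numbers. For each contact pair observed in at least one receptor, a 2×2
table counts coupled/non-coupled receptors with/without the contact, and
the enrichment is the natural-log odds ratio ln((AA·DD)/(BB·CC)) — positive
means the contact is more frequent in coupled receptors. The implementation
uses the summed-log form (log AA + log DD) − (log BB + log CC) so the
label-flip antisymmetry is exact in floating point. When any cell is zero,
0.5 is added to every cell (Haldane–Anscombe), which preserves that
antisymmetry. Per-transducer maps are MaxAbs-normalized to [−1, 1], summed
into unordered segment-pair signatures (with enriched/depleted pair
counts), and transducer families are clustered by average-linkage on
Euclidean distances between signature vectors, rows sorted alphabetically
so the tree is order-independent.

Because label permutation with the pair margins fixed makes the coupled
carrier count exactly hypergeometric, `enrichment_null_band()` computes the
permutation null analytically: an equal-tail central acceptance region
holding ≥ 95% of the null mass, inclusive at its endpoints. On a discrete
null this region is conservative (it typically holds 95.5–97% of the
mass), which is what one wants from an exact band; no permutation sampling
noise enters. A sampled permutation null (`enrichment_null()`) is kept for
diagnostics on aggregated maps.

## The embedded receptor space

For one layer, `fit_space()` projects the reference receptors by PCA and
runs K-means on the first two components (10 restarts under a fixed seed,
best inertia kept; the clustering uses the same two components that are
plotted). k is always the cardinality of the supplied functional label
set — never hard-coded, since label files differ in how many classes they
distinguish. Clusterings are scored against labels by normalized mutual
information, normalized by the arithmetic mean of the two entropies (the
common default; geometric/min/max are switchable). The best layer is the
NMI argmax, ties to the lowest layer. Queries and variants are projected
with the stored loadings, giving wild-type → variant trajectories in the
reference coordinate system.

## Variant effects

Variants arrive as `GENE/D294H` strings (1-based positions on the supplied
canonical sequence, reference residue validated) or as full replacement
sequences for isoforms. Coupling probability is computed for wild type and
variant at each model's layer; "coupled" means probability strictly above
0.5, and a switch is a gain (variant coupled, WT not) or loss (WT coupled,
variant not); otherwise the WT state is retained. Spliceforms are filtered
by retained 7TM fraction (annotated TM residues retained at identical
positions / total annotated TM residues; unknown when no annotation, in
which case only a zero coverage cutoff passes) and by maximal tissue
expression with an inclusive TPM ≥ 1 default.

## What the synthetic generators emulate — and what they do not

`make_synthetic_couplings()` emits Gaussian embeddings whose only structure
is a mean shift of `effect_size` in the planted head's 64 dimensions of the
planted layer for coupled receptors. Gaussian noise matches the linear
classifier's assumptions and makes the effect size interpretable as a
Cohen-style standardized shift. Activities are label-conditional Gaussians
straddling the assay threshold (e.g. logRAi ~ N(0, 0.3) coupled vs
N(−2, 0.3) non-coupled, resampled on the rare wrong side of the strict
cutoff) so binarization reproduces the planted labels exactly.
`make_synthetic_contacts()` plants pairs at 0.8 contact probability in
coupled receptors versus a 0.2 background, independently across pairs.
`make_synthetic_gpcrome()` separates class means by a configured Euclidean
distance (default studies use 30, comparable to the noise radius
√1280 ≈ 36, i.e. recoverable but not trivial) in exactly one layer. One
integer seed drives documented per-generator substreams
(`substream_seed()`), so generators are pure functions of (spec, seed) and
changing one never perturbs another.

None of this imitates real language-model statistics: real embeddings have
correlated dimensions, class imbalance, and signal spread across heads and
layers. Passing the planted-recovery tests shows the machinery is correct
and unbiased, not that real coupling is predictable at any particular
accuracy; reproducing published per-transducer performance would require
the original assay tables and the real embedding backend, which are out of
scope by design.

## Problem sizes and numerical choices in the test suite

The bundled studies use n = 200 receptors (balanced classes) with
effect size 2.0 for planted-head recovery and randomization nulls over 20
generator seeds; 500 receptors and a 40-position vocabulary (777 background
pairs) for contact enrichment; and 90 receptors in 3 classes for the layer
scan. These sizes give the recovery properties comfortable statistical
margins while keeping a full run in minutes on one core. Degenerate inputs
fail loudly: fewer than two receptors per class, zero-variance feature
matrices, classes smaller than the fold count, all-zero weight vectors and
all-zero contingency tables are rejected rather than patched.

## Known limitations

* The JSON model store serializes linear (logistic) models only; an SVC
  winner is stored through its logistic fallback, which is also what
  head-importance interpretation uses.
* Probability calibration for SVC is delegated to e1071's internal Platt
  scaling; calibrated probabilities near 0.5 can disagree with the class
  label implied by the decision boundary on tiny folds.
* The contact module consumes contact probabilities; it does not predict
  them, and generic-number annotation is read from a table, never computed
  from structure.
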