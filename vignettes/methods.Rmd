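---
title: "Multi-view similarity fusion and deep classification of drug–disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view similarity fusion and deep classification of drug–disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusedda)
```

## The model

`fusedda` scores drug–disease pairs for repurposing. The data model is a
bipartite link-prediction problem with side information: a binary
association matrix $Y \in \{0,1\}^{m \times n}$ over $m$ drugs and $n$
diseases, three binary feature views on the drug side (chemical
substructures, side effects, protein targets) and two on the disease side
(phenotype terms, protein targets). The pipeline has five stages, each with
an explicit contract.

### Per-view cosine similarity

Within one view, entity $i$ is a long sparse 0/1 vector. Similarity is
$\cos(x, y) = x \cdot y / (\lVert x\rVert\,\lVert y\rVert) \in [0, 1]$ for
binary input. Two conventions close the gaps cosine leaves open:

* **Empty profiles.** An all-zero row makes $\cos$ undefined ($0/0$). We
  define its similarity to every other entity as 0 — absence of features is
  absence of evidence, not evidence of dissimilarity — and keep the
  diagonal at 1, so downstream row normalization never meets a zero norm.
* **Exact diagonal.** The diagonal is forced to exactly 1 rather than
  computed, removing float jitter from the input of the fusion stage.

### Similarity network fusion

The per-view matrices are fused by iterative cross-diffusion. Each view $v$
is normalized into a full kernel
$P^{(v)}(i,j) = W(i,j) \,/\, 2\sum_{k \ne i} W(i,k)$ for $j \ne i$, with
$P^{(v)}(i,i) = 1/2$ — row-stochastic with half the mass pinned to the
diagonal, which keeps the diffusion numerically stable. An isolated entity
(zero off-diagonal mass) keeps all mass on its diagonal and triggers a
warning. A second, sparse kernel $S^{(v)}$ keeps only each row's $K$
largest off-diagonal entries (ties to the smaller index, for determinism)
renormalized to sum 1: local neighbourhoods are treated as the reliable
part of a similarity matrix. The update

$$P^{(v)} \leftarrow S^{(v)} \cdot \operatorname{mean}_{u \ne v} P^{(u)} \cdot S^{(v)\top}$$

diffuses the consensus of the other views through view $v$'s trusted
neighbourhoods; after each step the matrix is symmetrized and re-normalized
(a config flag disables per-iteration renormalization for comparison). After
$T$ iterations the fused matrix is the average over views, symmetrized.
Defaults are $K = 20$ (clamped to $m-1$ for small problems) and $T = 20$,
the customary operating point in the network-fusion literature; both are
exposed in `snf_config()`, together with an optional early-stop tolerance
on the maximum status change, which is also logged per iteration as a
convergence trace. Fused matrices are *not* rescaled to $[0,1]$ by default:
the classifier consumes relative, not absolute, magnitudes, and a rescale
would change nothing it can learn; the raw diffusion output is also easier
to audit against the row-stochastic contract.

The implementation is vectorized; the test suite holds it to within
$10^{-10}$ of an independently written naive loop reference on random
three-view instances.

### The pair table

Pair $(i, j)$ becomes one row: label $Y(i,j)$ and feature vector
$[\mathrm{UDRS}(i,\cdot),\ \mathrm{UDIS}(j,\cdot)]$ of length $m + n$, in
drug-major row order. With the two ID columns and the label the exported
table has $m + n + 3$ columns. The ID columns are metadata only — training
on entity indices would leak fold identity — so the classifier sees exactly
$m + n$ features.

### SMOTE balancing

Known associations and non-associations are imbalanced. SMOTE appends
synthetic minority rows $x + \lambda (x_{nn} - x)$, $\lambda \sim U(0,1)$,
where $x$ is a seeded-uniformly drawn minority row and $x_{nn}$ one of its
$k = 5$ nearest minority neighbours (Euclidean metric in the feature
space, ties to the smaller index), until minority/majority reaches the
balance rate 0.9 — precisely
$\max(0, \lceil 0.9\,n_{maj}\rceil - n_{min})$ appended rows. The minority
class is detected from the data rather than hard-coded, since synthetic
datasets can invert the imbalance. Balancing happens **inside each training
fold only**: oversampling before the split would plant synthetic neighbours
of test points in the training set, and the permutation control below would
not catch it, because the leak is geometric rather than label-borne. A flag
(`smote_in_folds = FALSE`) retains the leaky whole-dataset variant for
reproduction studies.

### The classifier

The default network is a dense stack: input $\to$ 5 hidden layers of 300
rectified-linear units, each followed by dropout 0.3 $\to$ one sigmoid
unit; binary cross-entropy loss; Nadam (learning rate 0.002, the standard
coefficients) on mini-batches of 64; 200 epochs at full scale. The hidden
activation and the 0.5 classification threshold are conventional choices
exposed in `network_config()`. A `conv1d` variant prepends one 1-D
convolution + max-pooling block over the feature vector for architecture
experiments; the dense stack is the default and the configuration the rest
of the package is validated with. `hidden_layers = 0` degenerates to
logistic regression, which is occasionally the right baseline.

Training is implemented directly on BLAS-backed matrix operations with an
explicit Nadam state, which buys two properties a heavyweight backend would
not give here: bit-exact reproducibility from one integer seed (weights,
shuffling, dropout and the validation split all derive from it) and zero
non-R dependencies. The per-epoch history (train/validation loss and
accuracy, from a stratified 30% monitoring split) is kept on the model and
exportable as CSV for learning-curve plots.

## Evaluation

Confusion counts use the 0.5 threshold; accuracy, precision
$TP/(TP+FP)$, recall $TP/(TP+FN)$ and the harmonic-mean F1 define a metric
as 0 when its denominator vanishes. AUROC is the trapezoidal area under
the tie-grouped ROC curve (the suite checks it against the Mann–Whitney
pair-counting statistic to $10^{-10}$, and against an external ROC
package); AUPR uses the step-wise average-precision rule, which unlike
trapezoidal PR interpolation never overstates the area between operating
points.

`cross_validate()` runs $k$-fold (default 5) over the pair rows, repeated
for a configurable number of rounds with fresh fold shuffles per round
(per-round sub-seeds); per-fold and aggregate metrics plus dispersions are
reported, and pooled last-round curves are exported. Folds are over pairs,
not drugs; a drug-disjoint split answers a different question (cold-start
drugs) and is left to the new-drug experiment.

The **new-drug experiment** takes every drug with exactly one known
indication, withholds that association, and asks whether the retrained
model ranks the withheld disease first among all $n$ candidates (ties to
the smaller index). The default trains one shared model with all the
cohort's labels removed — one training run instead of one per drug — and a
`per_drug` mode retrains per drug. A `score_matrix` argument bypasses
training entirely so the ranking logic can be driven by the generator's
ground-truth affinities, giving the experiment an exact enumeration oracle.

## The synthetic benchmark

`generate_synthetic()` plants recoverable structure: drugs are assigned
round-robin to $G$ groups and diseases to $H$ groups; each group draws one
random binary prototype per view, and an entity's profile is its prototype
with each bit flipped with probability $\varepsilon$; a random binary
$G \times H$ compatibility table $C$ (resampled until both outcomes occur,
else $Y$ would be single-class and untrainable) sets the association
probability of pair $(i,j)$ to $p_{hi}$ when
$C(g_i, h_j) = 1$ and $p_{lo}$ otherwise. The per-pair probability is
returned as the ground-truth affinity matrix. An optional
`singleton_fraction` of drugs is post-processed to exactly one association
(their highest-affinity disease, ties to the smaller index), populating the
new-drug cohort; the default is 0 so the plain block model is undistorted.

The canonical conditions are $m = 60$, $n = 40$, $G = H = 4$,
$\varepsilon = 0.05$, $p_{hi} = 0.9$, $p_{lo} = 0.02$, with view widths
64/48/32 (drug) and 48/32 (disease) — deliberately different per view so
shape bugs surface. At these settings the within-group minus between-group
cosine margin is comfortably positive ($> 0.2$), so the pipeline *should*
recover the structure, and the suite asserts that it does: mean test-fold
AUROC $\ge 0.85$ at 30 training epochs, and AUROC within $[0.43, 0.57]$
after label permutation (`permute_labels()`), the negative control that
guards against leakage anywhere in the pipeline.

What the generator does **not** emulate: real fingerprint bit correlation
(Tanimoto-style substructure dependence), heavy-tailed feature marginals,
vocabulary structure in phenotype terms, and the extreme sparsity of real
association matrices (≈1% versus ~30–45% here). Passing tests therefore
demonstrate that the machinery is correct and recovers planted structure —
not that the published external-benchmark figures transfer; those
benchmarks require curated downloads that are out of scope.

## Numerical and design choices

* **Entity order.** The association matrix fixes the canonical drug and
  disease order; profiles are re-indexed to it and mismatched entity sets
  are an error, never silently dropped.
* **Serialization.** Similarity matrices are written with 12 significant
  digits, reproducing entries to well within $10^{-12}$ absolute on read.
  Read-back symmetrizes away formatting jitter.
* **Tie-breaks** (KNN neighbours, SMOTE neighbours, disease ranking) are
  uniformly "smaller index first", making every stage deterministic.
* **Seeds.** Every stochastic stage takes its own seed; `cross_validate()`
  derives per-round and per-fold sub-seeds from the master seed, so a
  reported number is reproducible from the run configuration alone. All
  seeding is scoped (`withr`), leaving the caller's RNG state untouched.
* **Degenerate inputs.** All-zero association matrices warn and flow
  through (every stage downstream of $Y$ checks class presence);
  single-class training tables, empty minority classes and
  $k_{neighbors} \ge$ minority size are errors with typed conditions.
* **Problem sizes in the suite.** Tests validate contracts at small sizes
  (oracle equivalence at $10 \times 10$ to $50 \times 200$; end-to-end at
  $60 \times 40$ with 30 epochs), chosen so the planted structure is
  recoverable and the oracles are cheap to enumerate; the full-scale
  operating point (200 epochs, 150 CV rounds) remains available through
  configuration.

## Known limitations

* The dense network at its published width ($5 \times 300$) is
  over-parameterized for the toy benchmark; it still trains in seconds per
  fold, but at real scale ($\approx 600 \times 300$ entities, $10^5$
  pairs) a session-length run should reduce `epochs` or rely on
  `early_stopping`.
* `per_drug` new-drug mode retrains once per cohort drug and scales
  accordingly.
* The pair table is dense ($m n \times (m + n)$); no out-of-core path is
  provided.
* ROC/PR areas require both classes in the evaluated fold; folds are
  label-agnostic, so at extreme imbalance a fold can degenerate (the
  affected metric is reported as `NA` and excluded from means).
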