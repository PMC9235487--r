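---
title: "Extracting and auditing binding rules from black-box sequence classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and auditing binding rules from black-box sequence classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqanchors)
```

## The problem

Machine-learning models that predict whether a T cell receptor (TCR) binds a
given epitope are usually black boxes: they predict well but say nothing about
*which* residues, at *which* positions, drive the prediction.  `seqanchors`
turns any such classifier into a set of global, human-readable if-then rules
and then audits those rules quantitatively.  The only requirement on the model
is a batch `predict` contract: a function from amino-acid sequences to labels
in `{binding, non-binding}`.  Everything model-specific (BLOSUM or SMILES
encodings, neural-network internals) stays behind that contract.

The pipeline has four stages:

1. **Split.** The model labels every sample; samples are partitioned into the
   *binding* and *non-binding* splits.  All later stages run per split,
   because binding and non-binding rules are expected to differ.
2. **Cluster.** Each split is clustered under a sequence distance
   (Levenshtein by default).  The medoid of each cluster — an actual sample
   minimizing total distance to its cluster — becomes the representative
   instance to be explained.
3. **Explain.** For each medoid an *anchor* is computed: a conjunction of
   `(position, amino acid)` predicates such that perturbations of the medoid
   satisfying the rule receive the medoid's prediction with high probability
   (the rule's *precision*).
4. **Audit.** The rule set is evaluated for faithfulness, overlap and
   completeness at three levels, mapped onto FR/CDR regions, and rendered
   against sequence logos.

## The anchor model

An anchor for instance $x$ with model prediction $f(x)$ is a predicate set
$A$ with

$$\mathrm{prec}(A) \;=\; P_{z \sim \mathcal{D}(x, A)}\big[f(z) = f(x)\big] \;\ge\; \theta,$$

where $\mathcal{D}(x, A)$ is a perturbation distribution that holds the
positions in $A$ fixed.  Precision can only be estimated by sampling, so the
guarantee is statistical: the search certifies
$P[\mathrm{prec}(A) \ge \theta] \ge 1 - \delta$ using Kullback–Leibler
(Chernoff) confidence bounds on the Bernoulli precision estimate, and treats
the choice among candidate predicates as a best-arm-identification bandit
(KL-LUCB) with tolerance $\tau$: arms are pulled in batches of perturbations
until the best candidate's lower bound and the best challenger's upper bound
are within $\tau$.

The search is bottom-up beam search (default beam width 1, i.e. greedy):
starting from the empty rule, each round adds one candidate predicate
`(position, medoid symbol)`, selects the best extension(s) by the bandit,
then pulls the selected rule until $\theta$ lies outside its confidence
interval.  It stops as soon as a rule's lower bound clears $\theta$; if the
predicate budget or the pull budget is exhausted first, the
highest-lower-bound rule is returned flagged `below_threshold` (such rules
are still evaluated, but marked in reports).  Ties among equal candidates
break toward higher coverage, then lower position — more general rules are
preferred and the search is deterministic for a fixed seed.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `precision_threshold` | 0.9 | required precision lower bound $\theta$ |
| `delta` | 0.3 | admissible failure probability of the certificate |
| `tau` | 0.3 | bandit tolerance: how close competing arms may stay |
| `batch_size` | 100 | perturbations per bandit pull |
| `beam_width` | 1 | rules kept per round (1 = greedy) |
| `max_pulls` | 20000 | perturbation budget per anchor |

The 0.9/0.3/0.3 regime is the published setting for this class of analyses;
it favours precise rules at a tolerable certification cost.  Anchor
computation is the expensive stage of the pipeline (minutes to hours per
anchor at repertoire scale), which is why stages are checkpointed to disk
and a `--budget` flag caps pulls per anchor.

### The perturbation distribution

The original anchors formulation leaves the perturbation scheme to the
application.  Here, each position outside the rule is independently, with
probability $1/2$, replaced by a draw from the *empirical per-position symbol
distribution of the pool* (by default, the instance's own prediction split);
otherwise it keeps the instance's symbol.  The marginal probability that a
free position still matches the instance is therefore
$\tfrac12 + \tfrac12 q$, with $q$ the pool frequency of the instance's
symbol — a closed form the test suite verifies at $n = 10{,}000$.  This
choice preserves the positional composition of the repertoire (perturbations
look like plausible padded TCR frames, not uniform noise) and is
configurable: the pool may be the full dataset instead of the split.

A consequence worth knowing: positions that are near-fixed in the pool are
almost never perturbed away, so predicates on them cannot be distinguished
from the background and will not be selected — precision is always relative
to the stated perturbation distribution.

## Clustering choices

Distances are computed on raw residues; `<PAD>`/`<START>`/`<STOP>` tokens are
stripped first, since edit distance on padding is meaningless.  k-medoids
(PAM), agglomerative (complete linkage by default) and OPTICS run on the
precomputed distance matrix; BIRCH is registered for numeric feature vectors
only and errors on a distance matrix.  Silhouette (the default criterion,
defined for arbitrary distances) drives the hyperparameter sweep; the
Davies–Bouldin index is available for feature-space clusterings.  OPTICS
noise points (label −1) get no medoid and no anchor: a noise "cluster" has no
meaningful representative.  Medoid ties break to the lexicographically
smallest id.

Because no OPTICS, LLE or BIRCH implementation is available among the
package's allowed dependencies, compact standard versions are implemented
internally: OPTICS as reachability ordering with a DBSCAN-style cut at
$\epsilon$; LLE as k-nearest-neighbour reconstruction weights plus bottom
eigenvectors; BIRCH as a single sequential clustering-feature pass (no CF
tree) followed by average-linkage agglomeration of subcluster centroids —
adequate at desk scale, not tuned for millions of samples.  Consensus
clustering is the package's own choice where the field delegates to external
tooling: a co-association matrix (fraction of input clusterings placing a
pair together), average-linkage agglomeration of `1 − co-association`, cut
at the floor of the median input cluster count; it is invariant to
relabeling of the inputs.

## The audit

All metrics are computed over the full evaluation universe (both splits), so
false positives can come from the opposite split:

* **CL (cluster level)** — per rule, against the rule's own cluster.  A true
  positive must satisfy *only* that rule (exclusive semantics, quantified
  over all rules by default; both an inclusive variant and a
  same-split-only scope are exposed as flags, since the informal definitions
  in circulation differ).  Simultaneous perfect CL performance for all
  clusters is exactly faithfulness + no overlap + completeness.
* **CS (cluster-split level)** — per rule, against the rule's split: does
  satisfying the rule predict the split?
* **SP (split level)** — per split, against the union of its rules.

Zero-denominator ratios (common for small clusters) are reported as `NA`
with a warning, never coerced to 0.  Overlap is counted two ways: shared
predicates (same position *and* same symbol) and co-fulfillment (samples
satisfying both rules); rules conflicting at a shared position can never
co-fire.  Completeness is the histogram of applicable-anchor counts per
sample — ideally every sample sits in bin 1.

Region analysis assigns each predicate to the FR/CDR/Other/PAD/Start/Stop
interval containing its position *in the rule's own medoid annotation*, and
normalizes counts by the summed region length over the split's medoids.  The
counting unit is the predicate; a whole-rule mode (each rule contributes
$1/|A|$ per predicate) is available, since "how many rules fall in a region"
is ambiguous when one rule spans regions.  Region annotations are inputs
(germline alignment/numbering is out of scope); the synthetic generator
emits them.

## The synthetic world, and what a green test establishes

The generator emulates a TCR-β-like repertoire at desk scale: `n_samples`
sequences copied round-robin from `n_seed_sequences` uniformly random seeds,
each position independently replaced with probability `mutation_rate` by a
uniformly random symbol (possibly identical — so the expected Hamming
distance to the seed is exactly $L \cdot r \cdot (1 - 1/|\Sigma|)$), with a
shared FR/CDR interval template.  The default benchmark is n = 1000, frame
20, the 20-letter alphabet, 4 seeds, and two planted binding rules of three
predicates each at CDR positions, with the symbols of seeds 1 and 2.  The
mutation rate defaults to 0.05 — roughly one edit per 20-mer, a realistic
within-specificity-group divergence — chosen once, a priori.

The planted model predicts *binding* iff any planted conjunction is
satisfied, optionally XOR a Bernoulli label flip.  The flip is a
deterministic hash of the residue string and the model seed, so prediction
remains a pure function of the batch (the black-box determinism contract)
while unseen sequences still flip at the configured rate.

Two deliberate design points:

* **Identifiability.** Seeds are forced to differ pairwise at every planted
  rule position.  If two seeds collide there, the binding split is nearly
  pure at that position, the split-pool sampler almost never perturbs it,
  a strict sub-rule then genuinely exceeds the precision threshold, and the
  planted rule is unrecoverable *in principle*.  The constraint makes "the
  planted rule is the minimal high-precision rule" true by construction.
* **What green means.** Recovery of planted rules on this benchmark shows
  the search is correct and calibrated under its stated sampler.  It does
  not establish performance on real repertoires: real TCRs have variable
  lengths, phylogenetic and V(D)J-structured dependence between positions,
  and models whose decision surfaces are not conjunctions.  Those features
  are intentionally absent here.

## Numerical and degenerate-input conventions

KL bound inversion is by bisection to ~1e-8; the bandit's exploration rate
follows the standard $\beta(t) = \log(405.5\,K\,t^{1.1}/\delta)$ schedule;
Hoeffding bounds are available behind a flag.  Silhouette contributions of
singleton-cluster samples are 0; evaluation criteria error (rather than
guess) on single-cluster or all-noise labelings.  PAM is deterministic
(BUILD+SWAP), so the k-medoids seed is accepted but unused.  t-SNE runs in
exact mode (`theta = 0`) so fixed seeds give identical embeddings;
projections of three or fewer points are laid out on a line.  Figures are
written as SVG, which is byte-stable for identical input.  All randomness
flows from explicit seeds (default 0); the pipeline derives per-anchor seeds
from the global seed, and two runs with the same configuration are
byte-identical.

## Known limitations

* Anchor precision is defined relative to the perturbation distribution;
  changing the pool changes the rules.  This is inherent to the method, not
  an implementation artifact.
* The vacuous rule can legitimately clear the threshold for the majority
  split (perturbations of a non-binding medoid are mostly non-binding), in
  which case that split's anchors carry no positional information — visible
  in the audit as high SP recall with zero CL precision.
* OPTICS/LLE/BIRCH are compact reference implementations, quadratic or
  worse; for very large repertoires precompute distances once and prefer
  k-medoids/agglomerative.
* Multi-class models, probabilistic tie handling beyond thresholding, and
  germline region calling are out of scope; adapters must document their own
  decision rules.
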