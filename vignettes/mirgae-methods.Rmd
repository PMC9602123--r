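---
title: "Methods: sequence-similarity graph auto-encoding for miRNA-disease association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-similarity graph auto-encoding for miRNA-disease association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirgae` scores unknown miRNA-disease pairs by embedding both entity types
of the bipartite association graph into a common space and decoding edge
probabilities from embedding pairs. This vignette documents the model, its
assumptions, the tunable parameters, the synthetic data the tests rely on,
and the numerical and design choices a maintainer would want to know
about.

## Model

### Inputs

Three inputs drive the pipeline: a binary association matrix $A \in
\{0,1\}^{n_m \times n_d}$ (rows miRNAs, columns diseases; 1 = curated
association), the mature miRNA sequences (FASTA; `T` is canonicalized to
`U` at ingest), and a disease-to-MeSH tree-number mapping. Identifiers are
trimmed and lower-cased, and all matrices use lexicographic id order, so a
run is fully determined by its inputs and one integer seed.

### Sequence descriptors and similarity

Five encoders turn a sequence of length $N$ into a fixed-length vector:

* **3-mer composition** (64 dims): the count of each 3-mer window divided
  by $N$. Note the divisor is the sequence length, not the window count,
  so the vector sums to $(N-2)/N$; this is deliberate and tested.
* **CKSNAP** (96 dims): for each gap $g \in \{0,\dots,5\}$, the frequency
  of each of the 16 ordered nucleotide pairs at positions $(i, i+g+1)$,
  normalized by $N-g-1$ so each gap block sums to 1. Pairs are named in
  the conventional `T`-spelled alphabet.
* **Moran, Geary, normalized Moreau-Broto autocorrelation**
  ($22 \times \mathrm{nlag}$ dims each): the sequence is mapped to a
  per-position profile of dinucleotide property values (the dinucleotide
  starting at position $i$; pair properties such as Rise or Twist make
  single-base indexing meaningless), and each property is summarized at
  lags $1..\mathrm{nlag}$. Property values are z-scored across the 16
  dinucleotides before use - the standard Moreau-Broto normalization.
  Zero-variance profiles return 0 for Moran and Geary rather than an
  error: a constant standardized property is a valid, information-free
  input.

The packaged default property table
(`inst/extdata/rna_dinucleotide_properties.tsv`) carries the 22 indices
(helical step geometry, nearest-neighbour thermodynamics, hydrophilicity,
composition indicators) with values assembled from standard dinucleotide
physicochemical compilations; indices listed twice in the field's naming
convention (e.g. `Enthalpy (RNA)1`) are kept as distinct variant rows. The
table is an input: it can be replaced from file, and the test suite
exercises the encoders against synthetic tables so no test depends on the
shipped values.

Encoded vectors are compared by cosine similarity, Pearson correlation
(kept raw in $[-1, 1]$; the downstream model consumes arbitrary real
features, and clipping would discard anti-correlation information), or a
Euclidean transform $s = 1/(1+d)$ - monotone, mapping $[0,\infty)$ onto
$(0,1]$ with $d=0 \mapsto 1$ - because a distance is not a similarity and
the model expects larger-is-closer. The raw distance matrix remains
available for audit (`feature_distance()`). Combined-feature models
concatenate encoder vectors before the similarity step.

### Disease semantic similarity

MeSH tree numbers induce a DAG by prefix truncation (the parent of
`C04.588.894` is `C04.588`). The contribution of a node to a disease is
$\Delta^{g}$ where $g$ is the generation distance along the best
(maximizing) path and $\Delta = 0.5$; the disease's own nodes contribute
1, and its semantic value is the sum over its ancestor closure. Two
diseases are scored by the contributions of shared nodes divided by the
sum of their semantic values, giving 1 on the diagonal and 0 for disjoint
DAGs.

### GIP kernels and integration

Entities lacking sequence or MeSH data still have interaction profiles:
the Gaussian interaction-profile kernel scores
$\exp(-\sigma \lVert IP_i - IP_j \rVert^2)$ with bandwidth $\sigma$ equal
to a reference bandwidth (1) divided by the mean squared profile norm. The
integrated similarities MSim/DSim take the sequence/semantic entry when
*both* entities have source data and the GIP entry otherwise - the only
reading of "have sequence similarity" that makes the fallback
well-defined. An all-zero association matrix leaves $\sigma$ undefined and
is rejected.

### Graph auto-encoder

Node features are the integrated similarity rows ($F_m = $ MSim,
$F_d = $ DSim). A linear projection ($W_{\phi m}: E \times n_m$,
$W_{\phi d}: E \times n_d$) brings both sides into the same
$E$-dimensional space. Each of the $L$ encoder layers computes, for every
node, the degree-normalized sum of its bipartite neighbours' current
embeddings (degree-0 nodes aggregate to the zero vector, avoiding the
0/0), concatenates it with the node's own embedding, and applies a
per-side per-layer affine map followed by LeakyReLU. One layer is one
simultaneous (Jacobi-style) update of both sides from the pre-round
embeddings; a sequential update would make the result depend on which
side goes first, an order the model family leaves open. The decoder scores
pair $(i,j)$ as $\sigma(h_d(j)\, Q\, h_m(i)^\top)$ with a full $E \times
E$ trainable $Q$ ("$E$-dimensional" is read as $E \times E$; a diagonal
variant is not implemented).

Training minimizes
$-\sum_{(i,j)} \big[w^+ y \log \hat{s} + (1-y)\log(1-\hat{s})\big]$
over the training positives plus a once-per-run uniform sample of unknown
cells (`neg_ratio` per positive, default 1), by full-graph Adam. Scores
are clipped to $[10^{-7}, 1-10^{-7}]$ inside the loss only. The analytic
backward pass is verified against central finite differences to $10^{-4}$
relative error in the test suite.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `E` | 64 | embedding dimension; the configuration with `L = 6` is the best-performing preset of this model family (an `E = 256, L = 2` preliminary preset is equally expressible) |
| `L` | 6 | encoder layers (aggregation rounds) |
| `leaky_slope` | 0.01 | LeakyReLU negative slope; the function is named by the model family, the slope is the field's default |
| `learning_rate` | 1e-3 | Adam step size (optimizer details are this package's own choice) |
| `epochs` | 200 | full-graph gradient steps |
| `pos_weight` | 1 | cost-sensitive positive-term weight; sampling is already balanced, so up-weighting is off by default but exposed |
| `neg_ratio` | 1 | negatives per positive, sampled once per run |
| `clip_norm` | 5000 | global gradient-norm ceiling (see numerical choices) |
| `threshold` | 0.5 | classification threshold for Acc/Prec/Recall/F1 |
| `nlag` | 3 | autocorrelation maximum lag |
| `kmax` | 5 | CKSNAP widest gap |

All of these live in `gae_config()` and can be loaded from JSON
(`read_gae_config()`), so an experiment is reproducible from its config
file and seed.

## Evaluation protocol

Positive pairs are shuffled (seeded) into 5 near-equal folds. Per fold,
the training adjacency drops the test positives, the GIP kernels and
integrated similarities are recomputed **from the training adjacency
only**, and the model is trained from scratch. Test scoring uses the fold's
positives plus an equal-size seeded sample of never-used unknown pairs
(disjoint from the training negatives): a balanced sample keeps Acc/Prec
magnitudes interpretable, and the choice is recorded in the report. AUC is
the rank-based (Mann-Whitney) statistic - exact and tie-robust - while
exported ROC curves use the standard stepwise construction. Threshold
metrics follow the usual zero-denominator convention (0 with a warning).
Training negatives exclude nothing but the training positives, so a
held-out positive can occasionally be drawn as a training negative; this
mirrors the sampling contract of the model family and slightly *lowers*
measured performance (a conservative bias).

The leave-disease-out ranking removes every association of one target
disease, retrains, and ranks candidate miRNAs by score with a stable
tie-break (score descending, then id ascending) so top-k tables are
reproducible.

## Synthetic data: what it emulates and what it does not

`make_fixture()` plants signal in both channels the model uses:

* sequence families (one consensus per family, per-position substitution
  rate 0.08 at length 22 nt) aligned with
* association blocks (cell probability `p_in = 0.35` inside a paired
  family/block, `p_out = 0.02` elsewhere), aligned with
* MeSH subtrees (same-block diseases share code prefixes; the default
  tree uses branching 4, depth 4, because a 3-ary depth-3 tree cannot
  host 80 diseases in 6 block-aligned subtrees).

Profiles: `tiny` (12 × 8, unit tests), `default` (120 × 80, 6 blocks),
and `null` (default sizes, uniform cell probability 0.075 = the expected
density of the default profile, empty truth). Sizes were chosen so the
full 5-fold pipeline runs in well under a minute per seed on one CPU while
binomial density checks retain power.

What passing tests on these fixtures shows: the pipeline recovers planted
block structure well above chance, stays at chance on the no-signal
control, and never leaks test edges into fold training. What it does not
show: performance on real curated data. The generator does not mimic a
real database's heavy-tailed degree distribution, its name-mapping noise,
or real miRNA sequence statistics beyond length; block-constant
association probabilities are a much cleaner world than curation data.

An important quantitative consequence of the block design: given block
membership, cell labels are i.i.d., so the Bayes-optimal score has exactly
two levels and held-out AUC is capped. With the default densities, about
22 % of positives are out-of-block noise edges and about 12 % of unknown
cells are in-block, which caps AUC near 0.82 under the balanced-negative
protocol. `scripts/acceptance.R` computes this ceiling explicitly (the
truth-block oracle on the actual folds) next to the model's achieved AUC,
so the gap attributable to the model can be read off directly; the
trained model lands within a handful of points of the ceiling's
neighbourhood while the null control stays at chance.

## Numerical choices

* **Gradient clipping** (`clip_norm = 5000`): full-batch Adam on this
  architecture can spiral late in training (the bilinear logits are
  unbounded through the LeakyReLU stack); the global-norm ceiling sits
  near the 90th percentile of healthy gradient norms at the 120 × 80
  scale, so ordinary dynamics are untouched while divergence spirals are
  suppressed. `Inf` disables it.
* **Loss clipping** $\varepsilon = 10^{-7}$ applies inside the loss only;
  decoder outputs remain strict sigmoids in $(0,1)$.
* **Initialization**: scaled-uniform weights with bounds
  $\pm\sqrt{6/(\text{fan}_{in}+\text{fan}_{out})}$, zero biases, fully
  determined by the seed.
* **Degenerate cases**: zero-norm feature rows score 0 under
  cosine/Pearson (with a message, never NaN); zero-variance
  autocorrelation profiles return 0; degree-0 nodes aggregate to zero;
  an association matrix with no positives is rejected where the GIP
  bandwidth would be undefined.
* **Determinism**: one master seed is fanned out through
  `derive_seed(seed, tag)` so each consumer (folds, negatives, init, test
  negatives, generators) has an independent stream; re-running any
  entry point with the same inputs and seed reproduces outputs exactly.
* **Non-finite loss** raises a divergence error naming the epoch; there
  is no other early stopping, and no minibatching (full-graph updates
  suffice at these scales).

## Known limitations

* The model memorizes: the projection from full-rank similarity features
  can fit arbitrary labels (training AUC approaches 1), and the loss has
  no regularizer, so generalization rests entirely on the smoothness of
  the similarity inputs. On real data, early stopping or weight decay
  would be natural extensions; they are deliberately out of scope here.
* Disease names are matched case-insensitively after trimming; there is
  no fuzzy matching of curation names to MeSH descriptors - silent
  mismatches would be worse than dropped rows, and dropped rows are
  logged.
* No secondary-structure, thermodynamic-folding, target-gene or
  functional (MISIM-style) similarity channels; the sequence descriptors
  plus graph topology are the point of this model family.
* Whether combined-feature models should average similarity matrices
  instead of concatenating feature vectors is an open question in the
  field; concatenation is implemented.
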