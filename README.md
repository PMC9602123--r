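# mirgae

Predicting miRNA–disease associations from similarity networks with a
bipartite graph auto-encoder.

## The problem

Abnormal miRNA expression is implicated in many human diseases, but wet-lab
confirmation of individual miRNA–disease links is slow and expensive.
`mirgae` is for computational biologists who want to prioritize candidate
links from two cheap information sources: the mature miRNA **sequences**
themselves, and the **topology** of the already-known association network.
Given a binary association matrix `A` (miRNAs × diseases), the package
scores every unknown pair and ranks candidates for follow-up.

## The model

1. **miRNA sequence similarity (MSSM).** Each mature sequence is encoded by
   one of five descriptor families — 3-mer composition (64 dims), CKSNAP
   (composition of k-spaced nucleotide pairs, k = 5, 96 dims), and Moran,
   Geary and normalized Moreau–Broto autocorrelation over 22 standardized
   dinucleotide physicochemical indices (66 dims each) — and pairs of
   encodings are compared by cosine similarity, a Euclidean-distance
   transform `1/(1+d)`, or the Pearson correlation. Five encoders × three
   metrics give 15 candidate similarity matrices; CKSNAP + Pearson is the
   default.
2. **Disease semantic similarity (DSSM).** Diseases are located in the MeSH
   tree-number DAG; an ancestor at generation `g` contributes `Δ^g`
   (Δ = 0.5, best path) and two diseases are scored by the contributions of
   their shared ancestors relative to their total semantic values.
3. **GIP kernels (MGSM/DGSM).** Entities without sequence or MeSH data fall
   back to the Gaussian interaction-profile kernel
   `exp(−σ‖IP_i − IP_j‖²)` over rows/columns of `A`, with the bandwidth σ
   set by the mean squared profile norm.
4. **Graph auto-encoder.** Node features are rows of the integrated
   similarity matrices (MSim/DSim). After a linear projection to dimension
   `E` (default 64), each of `L` layers (default 6) aggregates a node's
   bipartite neighbours (degree-normalized sum), concatenates the aggregate
   with the node's own embedding, and applies an affine map + LeakyReLU.
   A bilinear decoder scores pair (i, j) as
   `σ(h_d(j) Q h_m(i)ᵀ)`. Training minimizes cost-sensitive binary
   cross-entropy over the known positives plus an equal-sized seeded sample
   of unknown pairs, with full-graph Adam.
5. **Evaluation.** Seeded 5-fold cross-validation over the positive pairs,
   with the GIP kernels recomputed per fold from the training adjacency
   only (no test-edge leakage), plus a leave-disease-out top-k ranking
   protocol.

Everything is testable offline: `make_fixture()` generates planted-block
synthetic data (sequence families aligned with association blocks and MeSH
subtrees) whose ground truth is known.

## Worked example

```r
library(mirgae)

fixture <- make_fixture("default", seed = 1)
#> <planted_fixture> profile 'default' | 120 miRNAs x 80 diseases | 701 positives (seed 1)

feats <- encode_features(fixture$sequences, "cksnap")
msim  <- feature_similarity(feats, "pearson")
dssm  <- semantic_similarity(fixture$dag)
round(msim[1:3, 1:3], 3)
#>           mir-f1-01 mir-f1-02 mir-f1-03
#> mir-f1-01     1.000     0.472     0.600
#> mir-f1-02     0.472     1.000     0.689
#> mir-f1-03     0.600     0.689     1.000

report <- cross_validate(fixture$associations, msim, dssm, gae_config(), seed = 1)
report
#> <cv_report> 5-fold cross-validation (seed 1)
#>   AUC      74.41 +/- 2.73 %
#>   ACC      69.62 +/- 2.07 %
#>   PREC     74.65 +/- 4.09 %
#>   RECALL   59.77 +/- 1.58 %
#>   F1       66.32 +/- 1.52 %
```

Same-family miRNAs are visibly more similar (0.47–0.69 vs ≈ 0.05 between
families), and the cross-validated AUC of 74.4 % sits close to this
fixture's Bayes ceiling of ≈ 82 % (out-of-block noise edges are
irreducibly unpredictable; the methods vignette quantifies this). The null
profile of the same generator stays at chance (AUC ≈ 50 %). Per-fold
detail, ROC curves and plots come from `tidy(report)`, `glance(report)`
and `autoplot(report)`; `rank_disease()` produces leave-disease-out top-k
candidate tables.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/mirgae.R synth --profile tiny --seed 1 --outdir fx
Rscript inst/cli/mirgae.R cv --fasta fx/sequences.fasta \
  --associations fx/associations.tsv --mesh fx/mesh.tsv --outdir out
```

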