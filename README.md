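# promembed

Promoter prediction for fixed-length DNA windows centered on a putative
transcription start site (TSS), combining per-nucleotide sequence encodings
with multi-scale embeddings of a learned sample-similarity graph and a
gradient-boosted tree classifier.

## The problem

Eukaryotic promoters — the regions around the TSS where RNA polymerase II
and transcription factors assemble — are classified against non-promoter
background (exon/intron sequence) from fixed windows such as
\[-249, +50\] bp. Purely local encodings ignore how *samples* relate to one
another; this package additionally builds a graph over all sequence samples
and embeds it, so each window is described both by its own sequence and by
its neighborhood structure in the cohort.

## The method

Each window of length L is encoded per nucleotide:

- **NCP** — chemical-property triple (r, h, f): ring structure (purine
  A/G = 1), hydrogen-bond strength (weak-pairing A/T = 1), functional group
  (amino A/C = 1); A = (1,1,1), C = (0,0,1), G = (1,0,0), T = (0,1,0).
- **ND** — running nucleotide density: position i carries
  count(s[1..i] = s[i]) / i.
- **EIIP** — electron–ion interaction pseudopotential energies
  T = 0.1335, A = 0.1260, G = 0.0806, C = 0.1340.
- **BPB** — bi-profile Bayes: position-specific nucleotide probabilities
  p⁺(i, n) and p⁻(i, n), estimated from *training* positives and negatives
  only (Laplace-smoothed).

The fused 7L-vectors x₁…x_m form a matrix X. Reconstruction weights W are
learned by minimizing

    ½ ‖X − (C∘W) X‖²_F + (μ/2) ‖(C∘W) e − e‖²,  W ≥ 0,

with C the k-nearest-neighbor indicator and ∘ the Hadamard product, via the
multiplicative update

    W_ij ← W_ij · (X Xᵀ + μ e eᵀ)_ij / ((C∘W) X Xᵀ + μ (C∘W) e eᵀ)_ij

on neighbor entries. The symmetrized support of W (made connected by a
nearest-neighbor backbone when needed) defines a weighted sample graph,
embedded at three scales: **node** (second-order biased random walks +
skip-gram with negative sampling), **community** (leading eigenvectors of
the modularity matrix B = A − d dᵀ/(2W_tot)) and **global** (truncated SVD
of log-ratio k-step transition matrices S^t, S = D⁻¹A). Local features and
embeddings are concatenated and classified by a gradient-boosted tree
ensemble (xgboost backend); evaluation reports Sen, Spe, Acc, MCC, Pre, F1,
rank-based AUC and Cohen's kappa.

A synthetic generator produces benchmark datasets: promoter-like positives
(GC 0.55, "TATAAA" planted 25–35 bp upstream of the TSS) versus
exon/intron-like negatives (order-1 Markov background, GC 0.45), in
balanced or imbalanced (e.g. 1:5) ratios, with a ground-truth motif
manifest.

## Worked example

```r
library(promembed)

cfg <- synthetic_config(n_pos = 200, n_neg = 200, seed = 11)  # 300-bp windows
ds  <- generate_dataset(cfg)
run <- run_pipeline(ds, seed = 11)
print(run)
```

```
pipeline_run ( 320 train / 80 test )
Sen 0.8750  Spe 0.7250  Acc 0.8000  MCC 0.6069
Pre 0.7609  F1  0.8140  AUC 0.9069  Kappa 0.6000
```

320 training rows were split 4:1 from the 400 windows (stratified by
class); the BPB profiles saw only the training rows, the similarity graph
was built transductively over all 400, and the held-out 80 windows were
scored. Sen/Spe are the positive/negative recall, MCC and kappa are
chance-corrected agreement (0 = chance, 1 = perfect), and AUC 0.907 means a
random held-out promoter outranks a random non-promoter 91% of the time.
The planted-motif signal is fully recoverable from the local features
alone (`run_pipeline(ds, scales = character(0), seed = 11)` reaches AUC
0.985 here); see the vignette for why the embedding stage can dilute an
already-strong local signal on this kind of benchmark.

Feature-combination ablations (local parts without the graph stage, and
embedding-scale subsets with all local parts) are driven by
`ablation_run()`, which returns a kappa table per condition. A thin CLI
with `simulate`, `run` and `ablate` subcommands lives at
`inst/cli/promembed-cli.R`.

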