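# LipidTE

Classification of lipid nanoparticle (LNP) transfection efficiency from
the ionizable lipid's SMILES string.

LNPs are the standard delivery vehicle for mRNA therapeutics, and the
ionizable lipid is the component that complexes the mRNA and drives
endosomal escape. Transfection efficiency (TE) is measured as reporter
luminescence (relative light units, RLU) and discretized: **satisfying**
TE at RLU ≥ 10 000 versus unsatisfying below it, or a four-class binning
of RLU at three configurable cuts. LipidTE implements the full modeling
pipeline for these targets, using only the ionizable lipid as input:

* **Representations** — a pinned 200-descriptor physicochemical vector
  (`expertDescriptors()`), count-based circular (Morgan) fingerprints
  folded into 2048 bins (`circularFingerprint()`), and a bespoke graph
  convolutional embedder over hydrogen-suppressed atom graphs with
  75-dimensional node features (`trainGCN()`, `extractEmbeddings()`).
  The GCN uses two degree-binned convolutions

  H<sub>v</sub><sup>(l)</sup> = ReLU( [D̃<sup>-1/2</sup> Â D̃<sup>-1/2</sup>
  H<sup>(l-1)</sup>]<sub>v</sub> W<sup>(l)</sup><sub>bin(deg v)</sub> ),
  &nbsp; Â = A + I,

  with five weight matrices per layer (one per neighbor count), sum
  pooling, a linear dense layer to a 32-dimensional molecule embedding,
  a softmax head trained with cross-entropy, dropout 0.3, and early
  stopping (patience 500 within 5000 epochs). Externally precomputed
  embeddings (e.g. from pretrained graph transformers or SMILES language
  models) plug in via `importExternalEmbeddings()`.
* **Classification** — a gradient-boosted decision-tree head over any
  single embedding (`trainClassifier()`; multiclass configuration fixed
  at depth 5, learning rate 0.005, 5000 iterations; `gridSearch()` for
  the binary task).
* **Evaluation** — stratified 5-fold cross-validation, lipid-family
  holdout (AUC reported absent for single-class held-out families), the
  imbalance-aware metric suite (one-vs-rest AUC, balanced accuracy,
  weighted F1, multiclass MCC), and paired one-sided t-tests between
  embedding methods across folds.
* **Embedding-space structure** — k-means clustering scored by
  normalized mutual information against lipid-family and TE labels, and
  a 2-D PCA projection (external projectors pluggable).
* **Synthetic library** — `generateLipidLibrary()` builds a
  family-structured ionizable-lipid library (families defined by
  hydrophobic-tail and zwitterion counts) with RLU driven by a known
  log-linear structure–activity rule plus noise, so every stage of the
  pipeline is testable without external data.

See the methods vignette (`vignettes/lipidte-methods.Rmd`) for the model
details, parameter choices and limitations.

## Worked example

```r
library(LipidTE)

# a 70-lipid synthetic library: 7 families, known activity rule
lib <- generateLipidLibrary(synthConfig(perFamily = 10, seed = 7))
head(lib[, c("id", "rlu", "binary_label", "multiclass_label", "family")], 3)
#>       id      rlu binary_label multiclass_label family
#> 1 F0_001 49.69643            0                0      0
#> 2 F0_002 94.48583            0                0      0
#> 3 F0_003 25.80659            0                0      0

embs <- list(cfp    = computeEmbeddings(lib, "cfp"),
             expert = computeEmbeddings(lib, "expert"))
report <- crossvalExperiment(lib, embs, label = "binary", k = 5, seed = 7,
                             config = gbtConfig(depth = 5,
                                                learningRate = 0.05,
                                                iterations = 300,
                                                loss = "binary", seed = 7))
report
#> EvalReport [cv]: 2 method(s), 5 fold(s)
#>  method       auc balanced_accuracy weighted_f1       mcc
#>     cfp 0.9645833         0.9107143   0.9133690 0.8304289
#>  expert 0.9604167         0.9232143   0.9275814 0.8572239

subset(methodComparisons(report), metric == "auc")
#>   method_a method_b metric p_value
#> 1      cfp   expert    auc   0.352
#> 5   expert      cfp    auc   0.648

clusterStructureSummary(lib, embs, seed = 7)
#>   method k nmi_family    nmi_te
#> 1    cfp 7  0.7812289 0.5344191
#> 2 expert 7  0.7729769 0.5356779
```

Both representations recover the planted tail-count signal (mean
cross-validated AUC ≈ 0.96 at this noise level); the paired fold-wise
t-test finds no significant difference between them (p = 0.35); and
k-means on either embedding aligns with the lipid families (NMI ≈ 0.78)
far better than with the TE classes — the qualitative pattern this kind
of family-structured library is built to exhibit.

A thin command-line front end over the same functions ships at
`inst/cli/lipidte`:

```sh
Rscript inst/cli/lipidte simulate  --out run --seed 7
Rscript inst/cli/lipidte featurize --out run --methods expert,cfp
Rscript inst/cli/lipidte evaluate  --out run --label binary
```

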