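# pgxlinker

Suggesting valid pharmacogenes from gene–drug–phenotype linked data.

Pharmacogenomics (PGx) catalogues which genes modulate drug response.
Curated knowledge bases annotate gene–drug associations with an evidence
level from 1 (well validated) to 4 (weak), leaving a long tail of level-3/4
candidates awaiting validation. `pgxlinker` prioritises those candidates by
learning from a heterogeneous linked-data graph — genes, drugs and
phenotypes from multiple sources, connected by typed edges (variant
annotations, indications, side effects, drug targets), decorated with
pathway and ATC attributes, and joined across sources by identifier-based
equivalence mappings.

Link prediction is recast as node classification: each candidate pair
(g, d) becomes a dedicated *pair node* wired to its gene and drug. Two
independent branches classify pair nodes:

* **Multi-instance path features + random forest.** A pair expands into a
  bag of categorical rows, one per combination of gene attribute, drug
  attribute, direct gene–drug link and (gene-side predicate, shared
  phenotype, drug-side predicate) triple. A probability forest scores
  instances, and the bag score is the signed weighted mean

  p_i = (1/n_i) Σ_j a_j · p_ij,  a_j = +1 if instance j is classified
  associated, −1 otherwise,

  so p_i ∈ [−1, 1] and bags mixing confident positives and negatives land
  near 0 rather than being forced positive (as `max` or the plain mean
  would).

* **Substructure-count graph kernels + SVM.** Edges are reified into
  labelled nodes, each pair node's depth-bounded neighbourhood is extracted
  (induced subgraph, or tree unfolding that repeats revisited vertices),
  and substructures are counted into sparse vectors: vertex-label multisets
  (bag of labels), directed-walk label sequences with multiplicity, or
  Weisfeiler–Lehman-style iteratively refined subtree patterns. Patterns
  rarer than a global minimum frequency are dropped. The kernel is the
  (cosine-normalised) dot product of pattern vectors; a C-SVC on the
  precomputed kernel, with the cost selected by inner cross-validation and
  probabilities from a sigmoid fitted on out-of-fold decision values,
  yields p_GK.

Both branches are evaluated with stratified 10-fold cross-validation
repeated 10 times, folds assigned at the pair level (a bag never straddles
a fold). Candidate lists are combined by intersecting each branch's top-k
and sorting by descending forest score.

Because the assembled corpus behind the original study mixes
license-restricted sources, the package ships a seeded synthetic generator
(`pgx_synth_generate`) that emulates the schema and signal structure —
dual-namespace entities with mappings, typed relation channels, a planted
shared drug-response phenotype per positive pair — so the whole pipeline is
testable at desk scale without any download.

## Worked example

```r
library(pgxlinker)

syn <- pgx_synth_generate(pgx_synth_config(
  n_genes = 60, n_drugs = 40, n_phenotypes = 90,
  n_positive = 30, n_negative_pool = 60, n_test = 12, seed = 1))
g <- syn$graph
g
#> <pgx_graph> 289 nodes, 915 edges, 57 mappings
#> AttributeValue           Drug           Gene      Phenotype
#>             42             52             78            117

pairs <- rbind(syn$truth$positive_pairs[, c("gene","drug","label")],
               syn$truth$negative_pairs[, c("gene","drug","label")])
rows <- pgx_build_bags(g, pairs)
# 417 instance rows for 90 pairs: each pair is a bag of path combinations

cv <- pgx_crossvalidate(list(rows = rows, pairs = pairs), "rf",
                        folds = 10, repeats = 2, seed = 1)
cv
#> <pgx_cv_report> rf branch, 10-fold CV x 2 repeats
#>   weighted F = 0.869 (sd 0.015)   macro F = 0.856   AUC = 0.896   RMSE = 0.342

model <- pgx_train_forest(pgx_build_matrix(rows), seed = 1)
test_rows <- pgx_build_bags(g, syn$truth$test_pairs[, c("gene","drug","label")])
sc <- pgx_score_pairs(model, test_rows)
head(sc[order(-sc$score), ], 3)
#>                  pair_id     score      prob
#> 2 gena:g0002|druga:d0011 0.8461044 0.9230522
#> 6 gena:g0010|druga:d0001 0.6905576 0.8452788
#> 4 gena:g0008|druga:d0001 0.6352865 0.8176432
```

`score` is the signed bag score p_RF: the top candidates are the weakly
validated pairs whose graph neighbourhood most resembles the well-validated
positives; `prob = (score + 1) / 2`. The kernel branch
(`pgx_pair_kernel` + `pgx_train_svm`) scores the same candidates as p_GK,
and `pgx_combine_rankings(rf, gk, k = 20)` intersects the two top lists into
the final ranked table (`rank, gene, drug, p_RF, p_GK`).

A thin command-line front end over these functions is installed at
`inst/cli/pgxlinker.R` (subcommands `synth`, `build-graph`, `make-sets`,
`featurize`, `kernel`, `rank`, `combine`).

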