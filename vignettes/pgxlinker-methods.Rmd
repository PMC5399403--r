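---
title: "Suggesting pharmacogenes from linked data: models and design choices"
author: "pgxlinker authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suggesting pharmacogenes from linked data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxlinker)
```

## The problem

Pharmacogenomics (PGx) asks which genes explain inter-individual variability
in drug response. Curated knowledge bases annotate gene--drug associations
with an evidence level from 1 (well validated) to 4 (weak); only a small
minority reach level 1--2, while a long tail of level 3--4 candidates waits
for validation. `pgxlinker` treats the prioritisation of those candidates as
*link prediction on a heterogeneous linked-data graph*: genes, drugs and
phenotypes from multiple sources, connected by typed edges (variant--phenotype
relations, drug indications and side effects, drug--target links), decorated
with categorical attributes (pathway membership for genes, ATC classes for
drugs), and glued across sources by identifier-based equivalence mappings.

Link prediction is recast as node classification: each candidate pair becomes
a dedicated *pair node* wired to its gene and its drug, and training pairs are
wired to one of two class nodes (`associated` / `not associated`). Two
independent branches then classify pair nodes:

* a **multi-instance path-feature branch**: each pair expands into a bag of
  categorical rows (one row per combination of length-1 paths and attributes
  around the pair), a random forest scores instances, and a signed weighted
  mean aggregates instance scores into a bag score;
* a **graph-kernel branch**: each pair node's depth-bounded neighbourhood is
  extracted from the reified graph, substructures (label multisets, walks,
  iteratively refined subtrees) are counted into sparse vectors, and a C-SVC
  with the resulting dot-product kernel classifies pairs.

Finally the two branches' top candidate lists are intersected and ranked.

## Graph model

The graph is a typed, edge-labelled directed multigraph. Node labels are
compact `namespace:local_id` strings; each namespace carries a node type
(`Gene`, `Drug`, `Phenotype`, `AttributeValue`, `GeneDrugPairNode`,
`ClassNode`). Attribute values are modelled as nodes, not literals, so that
kernels can count them as labels. Files are read as N-Triples (plus a
prefixed-Turtle subset); blank nodes are rejected because the schema has no
use for them. Nodes with no incident edges are serialised as `rdf:type`
declarations so a round trip is lossless.

Cross-source equivalence uses per-namespace regular expressions that extract
a shared identifier (an NCBI-gene-like id, a CUI-like id); same-type nodes in
different namespaces with equal identifiers are declared equivalent. The
default materialisation is *mapping edges* (`px:mapped_to` in both
directions), which preserves provenance and lets kernel walks cross sources;
*contraction* onto a canonical node is available for the path-feature branch,
where it simplifies slot lookups. Contraction conserves the multiset of
non-mapping edges and is independent of mapping order (union--find with the
lexicographically smallest member as canonical representative).

Kernels explore predicates in one direction only, so edge directions can be
normalised before kernel computation: every predicate listed in the inversion
rules is reversed and renamed `<p>_inv`. Pair nodes are created with
*outgoing* structural edges (`px:has_gene`, `px:has_drug`), which already
makes them neighbourhood roots that reach the rest of the graph; the default
inversion rule set is therefore empty, and the mechanism is available for
schemas whose edges point the other way.

One deliberate deviation from a literal reading of the augmentation step:
class-membership edges are **excluded** from the graph used for kernel
computation (`pgx_pair_kernel` strips them). If they were kept, a training
pair's label would sit inside its own neighbourhood and leak into the kernel
during cross-validation; node-classification kernel frameworks likewise
remove instance-label triples before counting.

## Path features and the multi-instance bag

For a pair (g, d) the six feature slots are: the gene's attribute values, the
drug's attribute values, the predicates of direct gene--drug edges, and, for
every phenotype reachable from g by one gene--phenotype edge *and* from d by
one drug--phenotype edge, the (gene-side predicate, phenotype, drug-side
predicate) triple. One categorical row is emitted per element of the
cartesian product of the non-empty slot value sets; empty slots contribute
the reserved token `NA`, and a fully isolated pair still yields one all-NA
row so that it can be scored (as a maximally uninformative bag) rather than
silently dropped. Phenotype slots are restricted to *shared* phenotypes: the
alternative (all phenotypes of either member, independently) makes the row
count multiplicative in two unrelated degrees and describes paths that never
connect the pair. Slot values are read from the entity and all its declared
equivalents, since attributes are spread across provenance nodes.

An optional seventh slot (phenotype attributes, MeSH-class-like) is off by
default: it is the kind of feature that information-gain screening removes,
and the switch exists so that ablation remains testable.

Rows are one-hot encoded with a per-slot vocabulary **frozen at training
time**; test-time values unseen in training map to the slot's NA column, so
train and test matrices always share columns. Information gain
`H(class) - H(class | slot)` is computed in bits on the categorical slots
(before encoding); slots below a user threshold are dropped from rows and
encoding alike.

The forest is `ranger` (probability forests, single-threaded, seeded); the
package's contribution is the formatting and aggregation around it, not the
tree learner. Bag aggregation is the signed weighted mean: instance `j` of
bag `i` contributes `+p_ij` if the forest classifies it as associated and
`-p_ij` otherwise, and the bag score is the mean over the bag, hence always
in `[-1, 1]`. Unlike `max` or the plain mean, a bag mixing confident
positives and confident negatives lands near 0 instead of being forced
positive. The score is reported raw; `(p + 1) / 2` is used only where a
`[0, 1]` probability is needed (RMSE, display).

## The kernel engine

The kernel engine is written from scratch. Edges are first *reified*: each
edge `(u, p, v)` becomes `u -> node(p) -> v` with a fresh node labelled `p`,
so substructure counting ignores the RDF node/edge label distinction. All
depths below are counted in edges of the reified graph: reaching an entity
one predicate away from the root costs 2 reified edges, and the default
exploration depth 4 reaches entities two predicates away (gene-side and
drug-side phenotypes of a pair node).

Neighbourhoods come in two flavours. *Subgraph*: breadth-first reachable set
within the depth bound, each vertex once, induced adjacency. *Tree*: full
unfolding in which revisited vertices are repeated as fresh occurrences;
cycles terminate because depth is bounded. Child order is fixed (label, then
vertex id), so every traversal is deterministic. Tree unfolding has a hard
occurrence cap (default 1e5) and exceeding it is an error, never silent
truncation.

Three substructure statistics are counted into sparse pattern vectors:

* **bag of labels** -- the multiset of vertex-occurrence labels;
* **walks** -- every label sequence realised by a directed walk of `0..l`
  edges, counted with multiplicity (dot products must see counts, not
  presence); length-0 walks (bare labels) are included by default, behind a
  flag;
* **subtrees** -- Weisfeiler-Lehman-style iterative refinement: at iteration
  0 each occurrence's refined label is its own label; at iteration `h` it is
  the canonical string of its previous refined label plus the sorted multiset
  of its children's refined labels at `h - 1`. All refined labels at
  iterations `0..depth` are counted. Canonical strings (not hashed ids) are
  used as pattern keys so vectors are comparable across instances without a
  shared dictionary.

The root constraint restricts counting to substructures anchored at the root
occurrence. The minimum-frequency filter drops *pattern keys* whose total
count over the instance set falls below the threshold; this global,
pattern-level formulation keeps kernels comparable across instances and makes
the filter monotone (raising the threshold can only shrink support). A
vertex-removal formulation was rejected: deleting rare-label vertices rewrites
their parents' subtree patterns into new keys, so support would not shrink
monotonically.

Both walk counting (frontier dynamic programming over (end-vertex, sequence)
states) and subtree counting (bottom-up iterative refinement) are validated
against independent brute-force enumerations (recursive walk enumeration;
top-down recursive canonical forms) on hundreds of random small graphs, in
both neighbourhood modes, with and without the root constraint.

The kernel is the sparse dot product of pattern vectors, optionally cosine
normalised (all-zero vectors yield 0). It is symmetric and positive
semidefinite by construction; `pgx_train_svm` still verifies both before
fitting (tolerances 1e-8 relative asymmetry, -1e-6 relative minimum
eigenvalue) because users may supply their own matrices.

The SVM is `kernlab`'s C-SVC on the precomputed kernel. Class probabilities
come from a Platt-style sigmoid fitted by logistic regression on training
decision values; the probability only needs to be rank-faithful to the
margin, and this avoids the fragility of built-in probability models on
small folds.

## Evaluation protocol

Both branches are evaluated with stratified 10-fold cross-validation repeated
10 times. Folds are assigned at the *pair* level, so all instances of a bag
stay in one fold; a bag straddling folds is a hard error (leakage guard), and
duplicate pair identities co-fold. The fold seed of repeat `r` is
`bitwXor(seed, r)`, making each repeat individually reproducible. Within each
training fold the SVM cost `C` is selected by an inner stratified
cross-validation over a fixed grid (`0.1, 1, 10, 100`) maximising weighted F,
without touching the outer test fold; forest hyperparameters are not tuned
(the forest is robust at these sizes, and tuning it would multiply runtime
for no observed benefit on the synthetic study). Per repeat, predictions are
pooled over the outer folds and summarised as per-class precision/recall/F,
prevalence-weighted and macro-averaged F (both are reported, since "average
F" is ambiguous), rank-statistic AUC-ROC, and RMSE between the probability of
the positive class and the 0/1 truth.

Candidate ranking takes each branch's top-k pairs (default k = 20) by its own
score, keeps the intersection, sorts by descending forest score (ties:
descending kernel score, then lexicographic pair identity) and assigns
consecutive ranks.

## The synthetic study

Licensed sources cannot be redistributed, so the package ships a seeded
generator that emulates the *schema and signal structure* of the assembled
corpus -- never its real statistics. Defaults (chosen once, as the package's
study conditions): 200 genes, 100 drugs, 300 phenotypes; 95 positive pairs at
evidence level 1--2 and a 1:2 negative pool of 190, echoing the real corpus'
91/182 design at desk scale; 40 level-3/4 test pairs, half carrying the
planted signal; 30% of entities duplicated in a second namespace and joined
by equivalence mappings; Poisson(2) background gene--phenotype and
drug--phenotype edges per entity; pathway and ATC vocabularies of 20 and 25.

The planted association for a positive pair consists of (i) a shared
phenotype wired to both members -- the gene side with a causal-variant
predicate, the drug side with an indication -- drawn from a small recurrent
pool (5% of phenotypes), because drug-response phenotypes recur across
pharmacogenes; and (ii) placement of the pair in pharmacogene-like
subpopulations (a quarter of genes, a third of drugs), reflecting that real
pharmacogene pairs concentrate in recognisable entity families (CYP-style
genes, narrow-therapeutic-index drugs). Both components are governed by the
`signal` probability: at `signal = 0` positives are drawn uniformly and
nothing is planted, so they are statistically indistinguishable from
negatives (downstream AUC ~ 0.5), and at intermediate signal only the
carried fraction is distinguishable.

Background edges emulate the semantics of real sources, where relation types
differ in meaning but not in marginal frequency. Every gene carries
causal-variant edges: pharmacogene-pool genes aim them at the recurrent
drug-response pool, other genes at Mendelian-like phenotypes, and
nonspecific association edges flow into the pool from everywhere at matched
intensity (the balancing rates equal the expected planted increment per pool
entity, so annotation intensity is even across subpopulations in
expectation). Drug-side indications and side-effects mirror the same
structure. The consequence, intended and worth stating plainly: no single
label frequency -- a predicate, a phenotype identifier, an attribute value --
identifies an association by itself; what discriminates is which relation
type points at which phenotype family (and, for the path-feature branch, the
shared-phenotype conjunction). This is the regime in which substructure
kernels are the right tool, and it mirrors real linked data, where
indications, side effects and variant annotations are ubiquitous and only
their configuration around a pair is informative.

The exclusion list emitted with a fixture contains every pair wired with any
gene--drug edge or planted signal, plus all positive and test pairs
(interaction databases subsume the curated positive source); negatives are
sampled uniformly outside it, sorted-then-shuffled under an explicit seed so
results are platform-stable.

What passing tests on this generator do **not** show: robustness to the
degree distributions, annotation sparsity, inter-source inconsistency and
label noise of real linked data. The generator emulates schema and signal
structure only; headline numbers published on the licensed corpus are not
reproducible here and are not targets of the test suite.

## Numerical and protocol choices

* Evidence levels: "best" level is the numerically smallest (level 1 is the
  strongest), per the standard worked example of a gene whose variants reach
  a drug at levels 1--4 and collapse to level 1.
* Negative sampling pools are the entities listed in the seed pair table, not
  all graph entities.
* Test pairs overlapping training genes or drugs are not filtered; nothing in
  the protocol requires it, and the overlap mirrors the real prioritisation
  setting.
* Whether length-0 walks belong in the walk kernel is genuinely open; they
  are included by default and isolated behind
  `include_zero_length_walks = FALSE`.
* Problem sizes used by the test suite and the acceptance script -- the
  default fixture for parameter recovery, a 60-gene/40-drug fixture for the
  kernel design-space comparison, 200 random graphs for oracle equivalence --
  were chosen so the full study runs comfortably on a single core while
  keeping every estimate stable across seeds.
* The kernel design-space comparison fixes `C = 1` across kernel
  configurations: the comparison is about substructure and root-constraint
  choices, and letting each configuration re-tune `C` would confound it with
  the inner search's variance on a small fixture.
* `combine_rankings` accepts scores on either the `[-1, 1]` bag scale or a
  `[0, 1]` probability scale and never rescales silently.

## Known limitations

* The Turtle reader covers the prefixed subset the fixtures use (`@prefix`,
  `;`/`,` continuations, literals with datatype/language tags); it is not a
  full Turtle parser, and blank nodes are rejected by design.
* Subtree pattern keys are full canonical strings; at large refinement depth
  on dense graphs they grow long. The committed depths (2--3) keep them
  short; a compressed shared dictionary would be the next step if deeper
  refinement were needed.
* Tree unfolding is exponential in pathological dense graphs; the occurrence
  cap turns that into a loud error rather than an silent approximation.
* The SVM branch scores pairs jointly present in the training kernel's
  pattern space; a test pair whose neighbourhood shares no pattern with any
  training pair gets a calibrated prior score, not an abstention.
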