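# In-code fixtures shared across test files.

# Small linked-data sample around one well-annotated pair: an EGFR-like gene
# present in two namespaces (attributes spread across both), a kinase-
# inhibitor-like drug, and one phenotype shared by gene and drug. The gene
# carries two pathway attributes, reaches the phenotype through two distinct
# variant predicates, the drug carries one ATC code, one indication edge to
# the phenotype, and the gene-drug antagonist link is direct.
make_sample_pair_graph <- function() {
  nodes <- data.frame(
    label = c("gena:EGFR", "genb:1956", "druga:gefitinib", "phena:C0007131",
              "pw:signal_transduction", "pw:immune_system", "atc:L01XE2"),
    type = c("Gene", "Gene", "Drug", "Phenotype",
             "AttributeValue", "AttributeValue", "AttributeValue"))
  edges <- data.frame(
    subject = c("gena:EGFR", "genb:1956", "gena:EGFR", "genb:1956",
                "druga:gefitinib", "druga:gefitinib", "gena:EGFR"),
    predicate = c("px:pathway", "px:pathway", "px:so_0001575",
                  "px:so_0001619", "px:atc_code", "px:indication",
                  "px:antagonist"),
    object = c("pw:signal_transduction", "pw:immune_system",
               "phena:C0007131", "phena:C0007131", "atc:L01XE2",
               "phena:C0007131", "druga:gefitinib"))
  g <- pgx_graph(nodes, edges)
  m <- data.frame(left = "gena:EGFR", right = "genb:1956",
                  method = "declared")
  g <- pgx_merge_equivalents(g, m, mode = "edge")
  pair <- data.frame(gene = "gena:EGFR", drug = "druga:gefitinib",
                     label = "associated")
  list(graph = g, pair = pair)
}

# Small synthetic study (fast to generate and cross-validate).
small_synth <- function(seed = 1, signal = 1, ...) {
  pgx_synth_generate(pgx_synth_config(
    n_genes = 60L, n_drugs = 40L, n_phenotypes = 90L, n_positive = 30L,
    n_negative_pool = 60L, n_test = 12L, signal = signal, seed = seed, ...))
}

training_pairs <- function(truth) {
  rbind(truth$positive_pairs[, c("gene", "drug", "label")],
        truth$negative_pairs[, c("gene", "drug", "label")])
}

pair_node_labels <- function(pairs) {
  paste0("pair:", pairs$gene, "__", pairs$drug)
}
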