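# Seeded synthetic pharmacogenomic linked-data generator: emulates the
# multi-source gene-drug-phenotype schema (dual namespaces with equivalence
# mappings, typed relation predicates, pathway/ATC attributes) and plants a
# shared-phenotype association signal for positive pairs.

GP_PREDICATES <- c("px:so_0001575", "px:so_0001619")  # SO-coded variant effects
DP_PREDICATES <- c("px:indication", "px:side_effect")
GD_PREDICATE  <- "px:target"
GENE_ATTR_PRED <- "px:pathway"
DRUG_ATTR_PRED <- "px:atc_code"

#' Configuration for the synthetic linked-data generator
#'
#' Defaults echo the real study conditions at desk scale: ~95 well-validated
#' positive pairs and a 1:2 negative pool (the real corpus has 91 positives
#' and negative sets of 91 and 182), an order of magnitude fewer entities
#' than the licensed sources, and a planted signal in which a positive pair's
#' gene and drug are wired to a shared phenotype.
#'
#' @param n_genes,n_drugs,n_phenotypes entity counts.
#' @param n_positive number of planted associated pairs (evidence level 1-2).
#' @param n_negative_pool number of sampled negatives (level absent).
#' @param n_test number of weakly validated candidate pairs (level 3-4).
#' @param signal probability in `[0,1]` that a positive pair carries the
#'   planted association (pool placement and shared-phenotype wiring); 0
#'   makes positives indistinguishable from negatives.
#' @param test_signal_fraction fraction of test pairs carrying the planted
#'   signal (the "true" candidates a ranker should surface).
#' @param noise_edge_rate expected number of random gene-phenotype /
#'   drug-phenotype edges per entity (Poisson).
#' @param dual_namespace_fraction fraction of entities duplicated in a second
#'   namespace and joined by an equivalence mapping.
#' @param gene_attr_vocab,drug_attr_vocab sizes of the pathway-like and
#'   ATC-like attribute vocabularies.
#' @param seed integer seed; identical configs produce byte-identical output.
#' @return A `pgx_synth_config` list.
#' @export
pgx_synth_config <- function(n_genes = 200L, n_drugs = 100L,
                             n_phenotypes = 300L, n_positive = 95L,
                             n_negative_pool = 190L, n_test = 40L,
                             signal = 1, test_signal_fraction = 0.5,
                             noise_edge_rate = 2, dual_namespace_fraction = 0.3,
                             gene_attr_vocab = 20L, drug_attr_vocab = 25L,
                             seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
              n_phenotypes = as.integer(n_phenotypes),
              n_positive = as.integer(n_positive),
              n_negative_pool = as.integer(n_negative_pool),
              n_test = as.integer(n_test), signal = signal,
              test_signal_fraction = test_signal_fraction,
              noise_edge_rate = noise_edge_rate,
              dual_namespace_fraction = dual_namespace_fraction,
              gene_attr_vocab = as.integer(gene_attr_vocab),
              drug_attr_vocab = as.integer(drug_attr_vocab),
              seed = as.integer(seed))
  stopifnot(cfg$signal >= 0, cfg$signal <= 1, cfg$noise_edge_rate >= 0,
            cfg$dual_namespace_fraction >= 0, cfg$dual_namespace_fraction <= 1)
  if (any(unlist(cfg[c("n_genes", "n_drugs", "n_phenotypes", "n_positive",
                       "n_negative_pool", "n_test")]) < 0L))
    stop("all counts must be >= 0")
  class(cfg) <- "pgx_synth_config"
  cfg
}

#' Generate a synthetic pharmacogenomic graph with planted ground truth
#'
#' Builds a typed linked-data graph: gene/drug/phenotype entities (a fraction
#' duplicated in a second namespace with equivalence mappings, merged in edge
#' mode), pathway and ATC attribute edges, background gene-phenotype and
#' drug-phenotype edges, a sprinkling of gene-drug target edges, and -- for
#' each positive pair, with probability `signal` -- a planted association: a
#' shared phenotype, drawn from a small recurrent pool of drug-response
#' phenotypes (5% of phenotypes), wired to the gene with the causal-variant
#' predicate and to the drug with an indication. Carried pairs are placed in
#' pharmacogene-like subpopulations (a quarter of genes, a third of drugs)
#' whose background annotations aim the causal/indication predicates at the
#' recurrent pool, while other entities receive Mendelian-like causal edges
#' and nonspecific pool traffic at matched intensity -- so no single label
#' frequency identifies an association; the predicate-phenotype combination
#' does. The emitted exclusion list contains every pair wired with a
#' gene-drug edge or planted signal plus all positive/test pairs, and
#' negatives are sampled outside it.
#'
#' @param config a [pgx_synth_config()].
#' @return list with elements `graph` (a `pgx_graph`) and `truth` (lists of
#'   `positive_pairs`, `negative_pairs`, `test_pairs`, `annotations`
#'   (variant-level, collapsing back to the pair tables),
#'   `planted_shared_phenotypes`, `exclusion`).
#' @export
pgx_synth_generate <- function(config = pgx_synth_config()) {
  cfg <- config
  n_cells <- as.double(cfg$n_genes) * cfg$n_drugs
  if (cfg$n_positive + cfg$n_test > n_cells)
    stop("more positive+test pairs requested than gene x drug combinations")
  empty_pairs <- data.frame(gene = character(), drug = character(),
                            evidence_level = integer(), label = character())
  if (cfg$n_genes == 0L || cfg$n_drugs == 0L) {
    truth <- list(positive_pairs = empty_pairs, negative_pairs = empty_pairs,
                  test_pairs = empty_pairs,
                  annotations = data.frame(gene = character(),
                                           variant_id = character(),
                                           drug = character(),
                                           evidence_level = integer()),
                  planted_shared_phenotypes = list(),
                  exclusion = data.frame(gene = character(), drug = character()))
    return(list(graph = pgx_graph(), truth = truth))
  }
  with_preserved_rng({
    set.seed(cfg$seed)
    genes <- sprintf("gena:g%04d", seq_len(cfg$n_genes))
    drugs <- sprintf("druga:d%04d", seq_len(cfg$n_drugs))
    phenos <- sprintf("phena:p%04d", seq_len(cfg$n_phenotypes))
    pw <- sprintf("pw:pw%03d", seq_len(max(1L, cfg$gene_attr_vocab)))
    atc <- sprintf("atc:A%03d", seq_len(max(1L, cfg$drug_attr_vocab)))

    nodes <- data.frame(
      label = c(genes, drugs, phenos),
      type = rep(c("Gene", "Drug", "Phenotype"),
                 c(length(genes), length(drugs), length(phenos))))

    # pharmacogene-like subpopulations: carried positive pairs concentrate
    # in a quarter of genes and a third of drugs whose annotations target
    # the recurrent drug-response phenotype pool
    pg_pool <- genes[seq_len(max(1L, round(0.25 * cfg$n_genes)))]
    pd_pool <- drugs[seq_len(max(1L, round(0.30 * cfg$n_drugs)))]

    dual_of <- function(labels, ns2) {
      k <- round(cfg$dual_namespace_fraction * length(labels))
      if (k == 0L) return(NULL)
      picked <- sort(sample(labels, k))
      sub("^[a-z]+:", paste0(ns2, ":"), picked)
    }
    genes2 <- dual_of(genes, "genb")
    drugs2 <- dual_of(drugs, "drugb")
    phenos2 <- dual_of(phenos, "phenb")
    if (length(genes2))
      nodes <- rbind(nodes, data.frame(label = genes2, type = "Gene"))
    if (length(drugs2))
      nodes <- rbind(nodes, data.frame(label = drugs2, type = "Drug"))
    if (length(phenos2))
      nodes <- rbind(nodes, data.frame(label = phenos2, type = "Phenotype"))

    edges <- list()
    add_edges <- function(s, p, o) {
      if (length(s))
        edges[[length(edges) + 1L]] <<- data.frame(subject = s, predicate = p,
                                                   object = o)
    }
    # attributes: 1-2 pathway values per gene, one ATC code per drug;
    # dual-namespace nodes carry one attribute of their own
    n_attr <- 1L + rbinom(cfg$n_genes, 1L, 0.5)
    add_edges(rep(genes, n_attr), GENE_ATTR_PRED,
              sample(pw, sum(n_attr), replace = TRUE))
    if (length(genes2))
      add_edges(genes2, GENE_ATTR_PRED,
                sample(pw, length(genes2), replace = TRUE))
    add_edges(drugs, DRUG_ATTR_PRED, sample(atc, cfg$n_drugs, replace = TRUE))
    if (length(drugs2))
      add_edges(drugs2, DRUG_ATTR_PRED,
                sample(atc, length(drugs2), replace = TRUE))

    # background relation edges: mostly the generic variant-association
    # predicate on the gene side, with a minority of decoy causal-variant
    # edges to random phenotypes (so the causal predicate alone does not
    # identify an association -- only causal edges into the recurrent
    # phenotype pool do); mostly side-effects (some indications) on the
    # drug side
    pool <- phenos[seq_len(max(min(3L, cfg$n_phenotypes),
                               round(0.05 * cfg$n_phenotypes)))]
    nonpool <- if (length(phenos) > length(pool))
      setdiff(phenos, pool) else phenos
    # background relation edges emulate source semantics: every gene has
    # causal-variant edges -- pharmacogene-pool genes aim them at recurrent
    # drug-response phenotypes, other genes at Mendelian-like phenotypes --
    # and generic association edges flow into the pool from everywhere.
    # Predicate and phenotype labels are therefore individually ambiguous;
    # the predicate(phenotype) combination is what marks an association.
    # Drug-side indications and side-effects mirror the same structure.
    if (cfg$noise_edge_rate > 0 && cfg$n_phenotypes > 0L) {
      # expected planted edges per pool entity: matched on the other side
      # so annotation intensity (causal count, pool-phenotype count) is
      # even across subpopulations in expectation
      lam_g <- cfg$signal * (cfg$n_positive +
                               cfg$test_signal_fraction * cfg$n_test) /
        length(pg_pool)
      lam_d <- cfg$signal * (cfg$n_positive +
                               cfg$test_signal_fraction * cfg$n_test) /
        length(pd_pool)
      channel_edges <- function(entities, in_pool, specific_pred,
                                generic_pred, lam) {
        k <- rpois(length(entities), cfg$noise_edge_rate)
        subj <- rep(entities, k)
        pooled <- rep(in_pool, k)
        specific <- rbinom(sum(k), 1L, 0.4) == 1L
        pred <- ifelse(specific, specific_pred, generic_pred)
        obj <- character(sum(k))
        tgt_pool <- (specific & pooled) | (!specific & rbinom(sum(k), 1L,
                                                              0.4) == 1L)
        obj[tgt_pool] <- sample(pool, sum(tgt_pool), replace = TRUE)
        obj[!tgt_pool] <- sample(nonpool, sum(!tgt_pool), replace = TRUE)
        add_edges(subj, pred, obj)
        # balancing edges for out-of-pool entities: Mendelian-like causal
        # annotations and nonspecific pool traffic
        outp <- entities[!in_pool]
        k2 <- rpois(length(outp), lam)
        add_edges(rep(outp, k2), specific_pred,
                  sample(nonpool, sum(k2), replace = TRUE))
        k3 <- rpois(length(outp), lam)
        add_edges(rep(outp, k3), generic_pred,
                  sample(pool, sum(k3), replace = TRUE))
      }
      channel_edges(genes, genes %in% pg_pool, GP_PREDICATES[1L],
                    GP_PREDICATES[2L], lam_g)
      channel_edges(drugs, drugs %in% pd_pool, DP_PREDICATES[1L],
                    DP_PREDICATES[2L], lam_d)
    }
    # background gene-drug target edges (all go on the exclusion list)
    n_gd <- round(0.1 * min(cfg$n_genes, cfg$n_drugs))
    gd_idx <- if (n_gd > 0L) sample.int(n_cells, n_gd) else integer()
    gd_g <- genes[((gd_idx - 1L) %% cfg$n_genes) + 1L]
    gd_d <- drugs[((gd_idx - 1L) %/% cfg$n_genes) + 1L]
    add_edges(gd_g, GD_PREDICATE, gd_d)

    # positive and test pairs: disjoint cells of the gene x drug grid.
    # A pair that carries the planted association is drawn from the
    # pharmacogene-like pools; one that does not is drawn uniformly.
    pos_carry <- runif(cfg$n_positive) < cfg$signal
    test_carry <- runif(cfg$n_test) < cfg$test_signal_fraction * cfg$signal
    carry_all <- c(pos_carry, test_carry)
    n_pairs <- cfg$n_positive + cfg$n_test
    pool_cells <- as.vector(outer(match(pg_pool, genes),
                                  (match(pd_pool, drugs) - 1L) * cfg$n_genes,
                                  "+"))
    if (sum(carry_all) > length(pool_cells))
      stop("more carried pairs requested than pharmacogene-pool combinations")
    cell <- integer(n_pairs)
    picked <- sample(pool_cells, sum(carry_all))
    cell[carry_all] <- picked
    if (any(!carry_all)) {
      free <- setdiff(seq_len(n_cells), picked)
      cell[!carry_all] <- sample(free, sum(!carry_all))
    }
    pg_ <- genes[((cell - 1L) %% cfg$n_genes) + 1L]
    pd_ <- drugs[((cell - 1L) %/% cfg$n_genes) + 1L]
    pos_g <- pg_[seq_len(cfg$n_positive)]
    pos_d <- pd_[seq_len(cfg$n_positive)]
    test_g <- pg_[cfg$n_positive + seq_len(cfg$n_test)]
    test_d <- pd_[cfg$n_positive + seq_len(cfg$n_test)]

    planted <- list()
    plant <- function(gs, ds, carry) {
      for (i in seq_along(gs)) {
        if (!carry[i]) next
        ph <- sample(pool, 1L)
        add_edges(gs[i], "px:so_0001575", ph)
        add_edges(ds[i], "px:indication", ph)
        planted[[paste(gs[i], ds[i], sep = "|")]] <<- ph
      }
    }
    if (cfg$n_phenotypes > 0L) {
      plant(pos_g, pos_d, pos_carry)
      plant(test_g, test_d, test_carry)
    }

    positive_pairs <- data.frame(
      gene = pos_g, drug = pos_d,
      evidence_level = if (cfg$n_positive)
        sample(1:2, cfg$n_positive, replace = TRUE) else integer(),
      label = rep("associated", cfg$n_positive))
    test_pairs <- data.frame(
      gene = test_g, drug = test_d,
      evidence_level = if (cfg$n_test)
        sample(3:4, cfg$n_test, replace = TRUE) else integer(),
      label = rep("unknown", cfg$n_test))
    test_pairs$has_signal <- test_carry

    # variant-level annotations that collapse back to the pair tables:
    # each pair gets 1-3 variant rows, one at the pair's level, the rest
    # at weakly larger levels.
    make_ann <- function(pp) {
      if (!nrow(pp)) return(data.frame(gene = character(),
                                       variant_id = character(),
                                       drug = character(),
                                       evidence_level = integer()))
      reps <- sample(1:3, nrow(pp), replace = TRUE)
      out <- pp[rep(seq_len(nrow(pp)), reps), c("gene", "drug",
                                                "evidence_level")]
      extra <- sequence(reps) > 1L
      out$evidence_level[extra] <- pmin(4L, out$evidence_level[extra] +
                                          sample(0:2, sum(extra),
                                                 replace = TRUE))
      out$variant_id <- paste0("rs", sample.int(1e6, nrow(out)))
      rownames(out) <- NULL
      out[, c("gene", "variant_id", "drug", "evidence_level")]
    }
    annotations <- rbind(make_ann(positive_pairs), make_ann(test_pairs))

    e <- do.call(rbind, edges)
    if (is.null(e)) e <- data.frame(subject = character(),
                                    predicate = character(),
                                    object = character())
    attr_labels <- setdiff(unique(e$object[e$predicate %in%
                                             c(GENE_ATTR_PRED,
                                               DRUG_ATTR_PRED)]), nodes$label)
    if (length(attr_labels))
      nodes <- rbind(nodes, data.frame(label = sort(attr_labels),
                                       type = "AttributeValue"))
    g <- pgx_graph(nodes, e, NULL)

    # equivalence mappings between namespaces (shared local identifier)
    m <- pgx_infer_mappings(
      g, c(gena = "^(g\\d+)$", genb = "^(g\\d+)$",
           druga = "^(d\\d+)$", drugb = "^(d\\d+)$",
           phena = "^(p\\d+)$", phenb = "^(p\\d+)$"))
    g <- pgx_merge_equivalents(g, m, mode = "edge")

    planted_key <- if (length(planted))
      vapply(strsplit(names(planted), "|", fixed = TRUE),
             function(x) paste(x, collapse = "\r"), "") else character()
    excl_key <- unique(c(paste(gd_g, gd_d, sep = "\r"),
                         paste(pos_g, pos_d, sep = "\r"),
                         paste(test_g, test_d, sep = "\r"), planted_key))
    excl_key <- sort(excl_key)
    parts <- strsplit(excl_key, "\r", fixed = TRUE)
    exclusion <- data.frame(gene = vapply(parts, `[`, "", 1L),
                            drug = vapply(parts, `[`, "", 2L))
    negative_pairs <- pgx_sample_negatives(genes, drugs, exclusion,
                                           cfg$n_negative_pool,
                                           seed = cfg$seed + 1000L)
    truth <- list(positive_pairs = positive_pairs,
                  negative_pairs = negative_pairs,
                  test_pairs = test_pairs,
                  annotations = annotations,
                  planted_shared_phenotypes = planted,
                  exclusion = exclusion)
    list(graph = g, truth = truth)
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits `graph.nt` (N-Triples), `pairs.tsv` (gene, drug, evidence level,
#' class for positives, negatives and test pairs), `annotations.tsv`
#' (variant-level rows), `exclusion.tsv`, and `manifest.json` with exact
#' counts. Re-loading `graph.nt` with [pgx_load_graph()] reproduces the graph.
#'
#' @param g a `pgx_graph`.
#' @param truth the ground-truth list from [pgx_synth_generate()].
#' @param dir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
pgx_write_fixture <- function(g, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pgx_write_graph(g, file.path(dir, "graph.nt"))
  pairs <- rbind(truth$positive_pairs[, c("gene", "drug", "evidence_level",
                                          "label")],
                 truth$negative_pairs[, c("gene", "drug", "evidence_level",
                                          "label")],
                 truth$test_pairs[, c("gene", "drug", "evidence_level",
                                      "label")])
  names(pairs) <- c("gene_label", "drug_label", "evidence_level", "class")
  write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$annotations, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$exclusion, file.path(dir, "exclusion.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tab <- table(g$nodes$type)
  manifest <- list(
    n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
    n_mappings = nrow(g$mappings),
    nodes_by_type = as.list(setNames(as.integer(tab), names(tab))),
    n_positive = nrow(truth$positive_pairs),
    n_negative = nrow(truth$negative_pairs),
    n_test = nrow(truth$test_pairs),
    n_exclusion = nrow(truth$exclusion),
    n_planted = length(truth$planted_shared_phenotypes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
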