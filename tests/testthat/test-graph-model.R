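test_that("N-Triples round trip preserves nodes, edges and mappings", {
  syn <- small_synth(seed = 3)
  g <- syn$graph
  path <- withr::local_tempfile(fileext = ".nt")
  pgx_write_graph(g, path)

  # independent line-oriented scan of the serialisation: one line per edge
  # plus one rdf:type declaration per isolated node
  lines <- readLines(path)
  n_iso <- sum(!(g$nodes$label %in% c(g$edges$subject, g$edges$object)))
  expect_length(lines, nrow(g$edges) + n_iso)
  expect_true(all(grepl("^<[^>]+> <[^>]+> (<[^>]+>|\"[^\"]*\") \\.$", lines)))

  g2 <- pgx_load_graph(path)
  expect_setequal(
    paste(g$edges$subject, g$edges$predicate, g$edges$object),
    paste(g2$edges$subject, g2$edges$predicate, g2$edges$object))
  expect_equal(nrow(g2$edges), nrow(g$edges))
  expect_equal(table(g2$nodes$type)[sort(unique(g$nodes$type))],
               table(g$nodes$type)[sort(unique(g$nodes$type))])
  expect_equal(nrow(g2$mappings), nrow(g$mappings))
  rep <- pgx_load_report(g2)
  expect_equal(rep$n_nodes, nrow(g2$nodes))
  expect_equal(rep$n_edges, nrow(g2$edges))
  expect_equal(rep$untyped_nodes, 0L)
})

test_that("empty input and basic counting behave as forced", {
  path <- withr::local_tempfile(fileext = ".nt")
  writeLines(character(), path)
  g <- pgx_load_graph(path)
  expect_equal(nrow(g$nodes), 0L)
  expect_equal(nrow(g$edges), 0L)

  writeLines(c(
    "<http://pgx.example.org/gena/g1> <http://pgx.example.org/vocab/so_0001575> <http://pgx.example.org/phena/p1> .",
    "<http://pgx.example.org/gena/g1> <http://pgx.example.org/vocab/pathway> <http://pgx.example.org/pathway/pw1> .",
    "<http://pgx.example.org/druga/d1> <http://pgx.example.org/vocab/indication> <http://pgx.example.org/phena/p1> ."),
    path)
  g <- pgx_load_graph(path)
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(sum(g$nodes$type == "Gene"), 1L)
  expect_equal(sum(g$nodes$type == "AttributeValue"), 1L)
})

test_that("the Turtle subset (prefixes, ';' and ',') parses; blank nodes are rejected", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix gena: <http://pgx.example.org/gena/> .",
    "@prefix phena: <http://pgx.example.org/phena/> .",
    "@prefix px: <http://pgx.example.org/vocab/> .",
    "gena:g1 px:so_0001575 phena:p1, phena:p2 ;",
    "        px:pathway <http://pgx.example.org/pathway/pw1> ."),
    path)
  g <- pgx_load_graph(path)
  expect_equal(nrow(g$edges), 3L)
  expect_setequal(g$edges$object, c("phena:p1", "phena:p2", "pw:pw1"))

  writeLines(c("@prefix px: <http://pgx.example.org/vocab/> .",
               "_:b1 px:p <http://pgx.example.org/gena/g1> ."), path)
  expect_error(pgx_load_graph(path), "blank nodes")
})

test_that("malformed triple files raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".nt")
  writeLines(c(
    "<http://a.org/x> <http://a.org/p> <http://a.org/y> .",
    "<http://a.org/x> <http://a.org/p \"unterminated ."), path)
  expect_error(pgx_load_graph(path), ":2")
})

test_that("nodes in undeclared namespaces are kept generic with a warning", {
  path <- withr::local_tempfile(fileext = ".nt")
  writeLines("<http://elsewhere.org/z1> <http://pgx.example.org/vocab/p> <http://elsewhere.org/z2> .",
             path)
  expect_warning(g <- pgx_load_graph(path), "generic")
  expect_true(all(g$nodes$type == "Generic"))
  expect_equal(pgx_load_report(g)$untyped_nodes, 2L)
})

test_that("identifier-based mapping inference matches shared ids of the same type only", {
  nodes <- data.frame(
    label = c("gena:1956", "genb:1956", "gena:7157", "phena:1956",
              "phenb:0042"),
    type = c("Gene", "Gene", "Gene", "Phenotype", "Phenotype"))
  g <- pgx_graph(nodes)
  ex <- c(gena = "^(\\d+)$", genb = "^(\\d+)$", phena = "^(\\d+)$",
          phenb = "^(\\d+)$")
  m <- pgx_infer_mappings(g, ex)
  # the shared id 1956 maps the two gene namespaces; the phenotype with the
  # same id is a different entity type and must not map
  expect_equal(nrow(m), 1L)
  expect_equal(m$left, "gena:1956")
  expect_equal(m$right, "genb:1956")

  # disjoint identifiers give the empty set
  g2 <- pgx_graph(data.frame(label = sprintf("gena:%d", 1:5),
                             type = "Gene"))
  expect_equal(nrow(suppressWarnings(pgx_infer_mappings(g2, ex))), 0L)
  expect_warning(pgx_infer_mappings(g2, c(genb = "^(\\d+)$")),
                 "matched 0")
})

test_that("edge-mode merging adds symmetric mapping edges; empty set is identity", {
  fx <- make_sample_pair_graph()
  g0 <- pgx_graph(data.frame(label = c("gena:a", "genb:a"), type = "Gene"))
  expect_identical(pgx_merge_equivalents(g0, NULL), g0)
  m <- data.frame(left = "gena:a", right = "genb:a", method = "declared")
  g1 <- pgx_merge_equivalents(g0, m, mode = "edge")
  expect_equal(nrow(g1$edges), 2L)
  expect_setequal(g1$edges$subject, c("gena:a", "genb:a"))
  # re-merging the same mapping is a no-op
  expect_equal(nrow(pgx_merge_equivalents(g1, m, mode = "edge")$edges), 2L)
  expect_error(pgx_merge_equivalents(
    g0, data.frame(left = "gena:a", right = "genb:zzz", method = "declared")),
    "absent")
})

test_that("contraction collapses equivalence chains onto one canonical node", {
  # chain a<->b, b<->c: union-find oracle says one class of three nodes
  nodes <- data.frame(label = c("gena:a", "gena:b", "genb:c", "phena:p"),
                      type = c("Gene", "Gene", "Gene", "Phenotype"))
  edges <- data.frame(subject = c("gena:a", "gena:b", "genb:c"),
                      predicate = "px:so_0001575",
                      object = "phena:p")
  g <- pgx_graph(nodes, edges)
  m <- data.frame(left = c("gena:a", "gena:b"),
                  right = c("gena:b", "genb:c"),
                  method = "declared")
  gc1 <- pgx_merge_equivalents(g, m, mode = "contract")
  expect_equal(sum(gc1$nodes$type == "Gene"), 1L)
  expect_equal(gc1$nodes$label[gc1$nodes$type == "Gene"], "gena:a")
  # non-mapping edge multiset conserved, rewired onto the canonical node
  expect_equal(nrow(gc1$edges), 3L)
  expect_true(all(gc1$edges$subject == "gena:a"))
  # contraction is independent of mapping order
  gc2 <- pgx_merge_equivalents(g, m[2:1, ], mode = "contract")
  expect_equal(gc1$nodes, gc2$nodes)
  expect_setequal(paste(gc1$edges$subject, gc1$edges$object),
                  paste(gc2$edges$subject, gc2$edges$object))
})

test_that("pair-node augmentation is exact, labelled, idempotent and reversible", {
  syn <- small_synth(seed = 5)
  g <- syn$graph
  pairs <- training_pairs(syn$truth)
  expect_identical(pgx_add_pair_nodes(g, pairs[0, ]), g)

  g2 <- pgx_add_pair_nodes(g, pairs)
  n_pair <- sum(g2$nodes$type == "GeneDrugPairNode")
  expect_equal(n_pair, nrow(pairs))
  cls_edges <- g2$edges[g2$edges$predicate == "px:is_a", ]
  expect_equal(nrow(cls_edges), nrow(pairs))
  expect_equal(sum(cls_edges$object == "class:associated"),
               sum(pairs$label == "associated"))
  expect_equal(sum(cls_edges$object == "class:not_associated"),
               sum(pairs$label == "not_associated"))
  # two structural edges per pair node
  pl <- pair_node_labels(pairs)
  expect_equal(sum(g2$edges$subject %in% pl &
                   g2$edges$predicate %in% c("px:has_gene", "px:has_drug")),
               2L * nrow(pairs))
  # idempotent
  expect_equal(nrow(pgx_add_pair_nodes(g2, pairs)$edges), nrow(g2$edges))
  # removal restores the original graph exactly
  g3 <- pgx_remove_pair_nodes(g2)
  expect_equal(g3$nodes, g$nodes)
  expect_equal(g3$edges, g$edges)
  # unknown-label pairs get no class edge
  gu <- pgx_add_pair_nodes(g, syn$truth$test_pairs[, c("gene", "drug", "label")])
  expect_equal(sum(gu$edges$predicate == "px:is_a"), 0L)
  expect_error(pgx_add_pair_nodes(
    g, data.frame(gene = "gena:nope", drug = pairs$drug[1],
                  label = "unknown")), "absent")
})

test_that("direction normalisation inverts, renames and is an involution", {
  syn <- small_synth(seed = 11)
  g <- syn$graph
  expect_identical(pgx_normalize_directions(g, character()), g)

  g1 <- pgx_normalize_directions(g, "px:indication")
  hit0 <- g$edges$predicate == "px:indication"
  expect_equal(nrow(g1$edges), nrow(g$edges))
  expect_equal(sum(g1$edges$predicate == "px:indication_inv"), sum(hit0))
  expect_equal(g1$edges$subject[g1$edges$predicate == "px:indication_inv"],
               g$edges$object[hit0])
  # applying the renamed rule restores the original edges
  g2 <- pgx_normalize_directions(g1, "px:indication_inv")
  expect_setequal(paste(g2$edges$subject, g2$edges$predicate, g2$edges$object),
                  paste(g$edges$subject, g$edges$predicate, g$edges$object))

  # inverting every predicate swaps the in/out degree sequences
  preds <- unique(g$edges$predicate)
  g3 <- pgx_normalize_directions(g, preds)
  expect_equal(sort(table(g3$edges$subject)), sort(table(g$edges$object)))
  expect_equal(sort(table(g3$edges$object)), sort(table(g$edges$subject)))
})
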