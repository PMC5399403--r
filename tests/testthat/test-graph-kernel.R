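test_that("reification follows the |V|+|E| / 2|E| law and preserves labels", {
  g0 <- pgx_graph()
  rg0 <- pgx_reify(g0)
  expect_length(rg0$labels, 0L)

  g1 <- pgx_graph(data.frame(label = c("x:a", "x:b"), type = "Generic"),
                  data.frame(subject = "x:a", predicate = "px:p",
                             object = "x:b"))
  rg1 <- pgx_reify(g1)
  expect_equal(sort(rg1$labels), c("px:p", "x:a", "x:b"))
  expect_equal(sum(lengths(rg1$adj)), 2L)

  set.seed(42)
  for (i in 1:10) {
    g <- random_small_graph(sample(2:5, 1), 15L)
    rg <- pgx_reify(g)
    expect_length(rg$labels, nrow(g$nodes) + 15L)
    expect_equal(sum(lengths(rg$adj)), 30L)
  }
})

test_that("neighbourhood extraction handles isolated roots, stars and cycles", {
  g_iso <- pgx_graph(data.frame(label = "x:a", type = "Generic"))
  rg <- pgx_reify(g_iso)
  for (mode in c("subgraph", "tree")) {
    nb <- pgx_neighborhood(rg, "x:a", pgx_kernel_config(neighborhood = mode))
    expect_equal(nb$labels, "x:a")
  }
  expect_error(pgx_neighborhood(rg, "x:zz"), "root")

  # star with k leaves at depth 1: root plus k reified edge nodes
  k <- 5L
  g_star <- pgx_graph(
    data.frame(label = c("x:r", paste0("x:l", 1:k)), type = "Generic"),
    data.frame(subject = "x:r", predicate = paste0("px:p", 1:k),
               object = paste0("x:l", 1:k)))
  rg <- pgx_reify(g_star)
  for (mode in c("subgraph", "tree")) {
    nb <- pgx_neighborhood(rg, "x:r",
                           pgx_kernel_config(depth = 1, neighborhood = mode))
    expect_length(nb$labels, 1L + k)
  }

  # directed 3-cycle a->b->c->a (on the original graph; depth counted on the
  # reified graph, so 6 reified edges close the cycle)
  g_cyc <- pgx_graph(
    data.frame(label = c("x:a", "x:b", "x:c"), type = "Generic"),
    data.frame(subject = c("x:a", "x:b", "x:c"), predicate = "px:p",
               object = c("x:b", "x:c", "x:a")))
  rg <- pgx_reify(g_cyc)
  nb_sub <- pgx_neighborhood(rg, "x:a",
                             pgx_kernel_config(depth = 6,
                                               neighborhood = "subgraph"))
  expect_length(nb_sub$labels, 6L)  # 3 vertices + 3 reified, each once
  nb_tree <- pgx_neighborhood(rg, "x:a",
                              pgx_kernel_config(depth = 6,
                                                neighborhood = "tree"))
  # hand unfolding: a,p,b,p,c,p,a -- the root is repeated as a fresh leaf
  expect_equal(nb_tree$labels,
               c("x:a", "px:p", "x:b", "px:p", "x:c", "px:p", "x:a"))
  expect_equal(pgx_count_labels(nb_tree),
               c(`px:p` = 3, `x:a` = 2, `x:b` = 1, `x:c` = 1))

  # the unfolding cap is a hard error, not truncation
  expect_error(
    pgx_neighborhood(rg, "x:a",
                     pgx_kernel_config(depth = 6, neighborhood = "tree",
                                       max_occurrences = 3)),
    "max_occurrences")
})

test_that("tree and subgraph neighbourhoods coincide on unique-path acyclic graphs", {
  # a small out-tree: every vertex reachable along exactly one path
  g <- pgx_graph(
    data.frame(label = paste0("x:n", 1:5), type = "Generic"),
    data.frame(subject = c("x:n1", "x:n1", "x:n2", "x:n2"),
               predicate = c("px:p1", "px:p2", "px:p1", "px:p3"),
               object = c("x:n2", "x:n3", "x:n4", "x:n5")))
  rg <- pgx_reify(g)
  a <- pgx_neighborhood(rg, "x:n1",
                        pgx_kernel_config(depth = 4, neighborhood = "tree"))
  b <- pgx_neighborhood(rg, "x:n1",
                        pgx_kernel_config(depth = 4,
                                          neighborhood = "subgraph"))
  expect_equal(sort(a$labels), sort(b$labels))
  expect_same_counts(pgx_count_walks(a, 4), pgx_count_walks(b, 4))
})

test_that("walk counting matches the reified-path worked example", {
  g <- pgx_graph(data.frame(label = c("x:a", "x:b"), type = "Generic"),
                 data.frame(subject = "x:a", predicate = "px:p",
                            object = "x:b"))
  rg <- pgx_reify(g)
  nb <- pgx_neighborhood(rg, "x:a", pgx_kernel_config(depth = 2))
  w <- pgx_count_walks(nb, 2)
  sep <- "\x1f"
  expect_same_counts(w, setNames(rep(1, 6), c(
    "px:p", paste0("px:p", sep, "x:b"), "x:a", paste0("x:a", sep, "px:p"),
    paste0("x:a", sep, "px:p", sep, "x:b"), "x:b")))
  wr <- pgx_count_walks(nb, 2, root_constraint = TRUE)
  expect_same_counts(wr, setNames(rep(1, 3), c(
    "x:a", paste0("x:a", sep, "px:p"),
    paste0("x:a", sep, "px:p", sep, "x:b"))))
  # single vertex, any length: one walk, its own label
  nb1 <- pgx_neighborhood(pgx_reify(pgx_graph(
    data.frame(label = "x:z", type = "Generic"))), "x:z")
  expect_equal(pgx_count_walks(nb1, 2), c(`x:z` = 1))
})

test_that("subtree refinement is order-free over children and counts leaves plainly", {
  # perfect binary depth-1 trees with swapped leaf labels refine identically
  mk <- function(l1, l2) {
    g <- pgx_graph(
      data.frame(label = c("x:r", paste0("x:", c(l1, l2))),
                 type = "Generic"),
      data.frame(subject = "x:r", predicate = c("px:p", "px:p"),
                 object = paste0("x:", c(l1, l2))))
    pgx_neighborhood(pgx_reify(g), "x:r",
                     pgx_kernel_config(depth = 2, neighborhood = "tree"))
  }
  expect_same_counts(pgx_count_subtrees(mk("u", "v"), 2),
                     pgx_count_subtrees(mk("v", "u"), 2))
  # a leaf contributes one pattern per refinement iteration
  nb1 <- pgx_neighborhood(pgx_reify(pgx_graph(
    data.frame(label = "x:z", type = "Generic"))), "x:z")
  st <- pgx_count_subtrees(nb1, 3)
  expect_length(st, 4L)
  expect_true(all(st == 1))
})

test_that("walk and subtree counts agree with brute-force enumeration on random graphs", {
  set.seed(20240901)
  for (trial in 1:60) {
    g <- random_small_graph(sample(2:5, 1), sample(1:7, 1))
    root <- sample(g$nodes$label, 1)
    mode <- sample(c("tree", "subgraph"), 1)
    d <- sample(1:4, 1)
    nb <- pgx_neighborhood(pgx_reify(g),
                           root, pgx_kernel_config(depth = d,
                                                   neighborhood = mode))
    for (rc in c(FALSE, TRUE)) {
      expect_same_counts(pgx_count_walks(nb, 4, rc),
                         oracle_walks(nb, 4, rc))
      expect_same_counts(pgx_count_subtrees(nb, 3, rc),
                         oracle_subtrees(nb, 3, rc))
    }
  }
})

test_that("root-constrained counts are sub-multisets of unconstrained counts", {
  set.seed(77)
  for (trial in 1:20) {
    g <- random_small_graph(4, 6)
    nb <- pgx_neighborhood(pgx_reify(g), sample(g$nodes$label, 1),
                           pgx_kernel_config(depth = 3,
                                             neighborhood = "tree"))
    w_all <- pgx_count_walks(nb, 3); w_root <- pgx_count_walks(nb, 3, TRUE)
    expect_true(all(names(w_root) %in% names(w_all)))
    expect_true(all(w_root <= w_all[names(w_root)]))
    s_all <- pgx_count_subtrees(nb, 2)
    s_root <- pgx_count_subtrees(nb, 2, TRUE)
    expect_true(all(names(s_root) %in% names(s_all)))
    expect_true(all(s_root <= s_all[names(s_root)]))
  }
})

test_that("minimum-frequency filtering is the identity at 0 and shrinks support monotonically", {
  syn <- small_synth(seed = 6)
  pairs <- training_pairs(syn$truth)[1:20, ]
  gp <- pgx_add_pair_nodes(syn$graph, pairs)
  ker <- pgx_pair_kernel(gp, pair_node_labels(pairs),
                         pgx_kernel_config(substructure = "bag_of_labels"))
  counts <- ker$counts
  expect_identical(pgx_filter_min_frequency(counts, 0), counts)
  prev <- counts
  for (mf in c(2, 5, 10, 50)) {
    cur <- pgx_filter_min_frequency(counts, mf)
    for (i in seq_along(cur)) {
      expect_true(all(names(cur[[i]]) %in% names(prev[[i]])))
    }
    prev <- cur
  }
})

test_that("kernel matrices are exact dot products, symmetric, PSD, unit-diagonal", {
  # closed-form cases
  v <- c(a = 2, b = 1)
  expect_equal(pgx_kernel_matrix(list(v, v), normalize = TRUE),
               matrix(1, 2, 2))
  disj <- list(c(a = 1), c(b = 3))
  expect_equal(pgx_kernel_matrix(disj, normalize = TRUE), diag(2))
  # dense linear-algebra oracle on random sparse vectors
  set.seed(9)
  pats <- paste0("q", 1:12)
  vecs <- lapply(1:5, function(i) {
    k <- sample(3:8, 1)
    setNames(as.numeric(sample(1:4, k, replace = TRUE)), sample(pats, k))
  })
  K <- pgx_kernel_matrix(vecs, normalize = FALSE)
  D <- matrix(0, 5, 12, dimnames = list(NULL, pats))
  for (i in 1:5) D[i, names(vecs[[i]])] <- vecs[[i]]
  expect_equal(K, unname(D %*% t(D)))
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-9)
  Kn <- pgx_kernel_matrix(vecs, normalize = TRUE)
  expect_equal(diag(Kn), rep(1, 5))
  # an all-zero vector normalises to 0 without dividing by zero
  K0 <- pgx_kernel_matrix(list(c(a = 1), setNames(numeric(), character())),
                          normalize = TRUE)
  expect_equal(K0[1, 2], 0)
})
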