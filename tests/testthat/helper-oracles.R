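# Brute-force oracles for substructure counting, independent of the
# package's frontier/refinement implementations.

ORACLE_SEP <- "\x1f"

# Exhaustive recursive enumeration of directed walks of 0..l edges.
oracle_walks <- function(nb, l, root_constraint = FALSE,
                         include_zero = TRUE) {
  acc <- new.env(hash = TRUE, parent = emptyenv())
  note <- function(key) {
    assign(key, (if (exists(key, envir = acc, inherits = FALSE))
      get(key, envir = acc) else 0) + 1, envir = acc)
  }
  dfs <- function(v, labs, len) {
    if (len > 0L || include_zero)
      note(paste(labs, collapse = ORACLE_SEP))
    if (len < l)
      for (ch in nb$adj[[v]]) dfs(ch, c(labs, nb$labels[ch]), len + 1L)
  }
  starts <- if (root_constraint) nb$root else seq_along(nb$labels)
  for (s in starts) dfs(s, nb$labels[s], 0L)
  keys <- ls(acc, sorted = TRUE)
  setNames(vapply(keys, get, 0, envir = acc), keys)
}

# Top-down recursive canonical rooted-subtree forms at refinement depths
# 0..depth, counted over all (or the root) vertices.
oracle_subtrees <- function(nb, depth, root_constraint = FALSE) {
  canon <- function(v, h) {
    if (h == 0L) return(nb$labels[v])
    kids <- vapply(nb$adj[[v]], canon, "", h = h - 1L)
    paste0(canon(v, h - 1L), "(", paste(sort(kids), collapse = ","), ")")
  }
  counted <- if (root_constraint) nb$root else seq_along(nb$labels)
  keys <- unlist(lapply(0:depth, function(h)
    vapply(counted, canon, "", h = h)))
  tab <- table(keys)
  setNames(as.numeric(tab), names(tab))
}

# Random small labelled multigraph (reified form has n_nodes + n_edges
# vertices); predicates repeat so label multisets are non-trivial.
random_small_graph <- function(n_nodes, n_edges) {
  nodes <- data.frame(label = paste0("x:n", seq_len(n_nodes)),
                      type = "Generic")
  edges <- data.frame(
    subject = sample(nodes$label, n_edges, replace = TRUE),
    predicate = sample(c("px:p1", "px:p2", "px:p3"), n_edges,
                       replace = TRUE),
    object = sample(nodes$label, n_edges, replace = TRUE))
  pgx_graph(nodes, edges)
}

expect_same_counts <- function(a, b) {
  a <- a[order(names(a))]; b <- b[order(names(b))]
  expect_identical(names(a), names(b))
  expect_equal(unname(a), unname(b))
}
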