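# Substructure-count graph kernels over pair nodes: edge reification,
# depth-bounded neighbourhood extraction (induced subgraph or tree
# unfolding), bag-of-labels / walk / subtree counting, global
# minimum-frequency pattern filtering, and sparse dot-product kernels.

SEQ_SEP <- "\x1f"  # label-sequence separator (never occurs in labels)

#' Kernel configuration
#'
#' @param depth neighbourhood exploration depth, counted in edges on the
#'   *reified* graph (an original predicate step costs 2 reified edges; the
#'   default 4 reaches entities two predicates away from the root).
#' @param substructure `"subtrees"`, `"walks"` or `"bag_of_labels"`.
#' @param neighborhood `"tree"` (cycles unfolded, vertices repeated) or
#'   `"subgraph"` (each vertex once, induced edges).
#' @param root_constraint count only substructures anchored at the root
#'   occurrence (tree neighbourhoods).
#' @param substructure_size maximum walk length / subtree refinement depth,
#'   in reified edges.
#' @param min_frequency drop patterns whose global count over the instance
#'   set falls below this (0 = keep all).
#' @param normalize cosine-normalise the kernel matrix.
#' @param include_zero_length_walks count length-0 walks (bare vertex
#'   labels) in the walk kernel.
#' @param max_occurrences hard cap on tree-unfolding size per neighbourhood;
#'   exceeding it is an error, never silent truncation.
#' @return A `pgx_kernel_config` list.
#' @export
pgx_kernel_config <- function(depth = 4L,
                              substructure = c("subtrees", "walks",
                                               "bag_of_labels"),
                              neighborhood = c("tree", "subgraph"),
                              root_constraint = FALSE,
                              substructure_size = 2L,
                              min_frequency = 0L,
                              normalize = TRUE,
                              include_zero_length_walks = TRUE,
                              max_occurrences = 1e5) {
  stopifnot(depth >= 1L, substructure_size >= 0L, min_frequency >= 0L)
  structure(list(depth = as.integer(depth),
                 substructure = match.arg(substructure),
                 neighborhood = match.arg(neighborhood),
                 root_constraint = isTRUE(root_constraint),
                 substructure_size = as.integer(substructure_size),
                 min_frequency = min_frequency,
                 normalize = isTRUE(normalize),
                 include_zero_length_walks = isTRUE(include_zero_length_walks),
                 max_occurrences = max_occurrences),
            class = "pgx_kernel_config")
}

#' Reify edges into labelled nodes
#'
#' Substructure counting ignores the RDF distinction between node and edge
#' labels: every edge `(u, p, v)` becomes `u -> node(p) -> v`, one fresh
#' reified node per edge occurrence carrying label `p`. The result has
#' `|V| + |E|` vertices and `2|E|` edges. Child adjacency is pre-sorted by
#' (label, vertex id) so all downstream traversals are deterministic.
#'
#' @param g a `pgx_graph`.
#' @return A `pgx_reified` list: `labels` (per vertex), `adj` (children
#'   lists), `index` (node label -> vertex id for original vertices).
#' @export
pgx_reify <- function(g) {
  nv <- nrow(g$nodes); ne <- nrow(g$edges)
  labels <- c(g$nodes$label, g$edges$predicate)
  index <- setNames(seq_len(nv), g$nodes$label)
  from <- c(unname(index[g$edges$subject]), nv + seq_len(ne))
  to <- c(nv + seq_len(ne), unname(index[g$edges$object]))
  adj <- vector("list", nv + ne)
  if (ne) {
    sp <- split(to, factor(from, levels = seq_len(nv + ne)))
    adj <- lapply(sp, function(ch)
      if (length(ch)) ch[order(labels[ch], ch)] else integer())
    names(adj) <- NULL
  }
  structure(list(labels = labels, adj = adj, index = index),
            class = "pgx_reified")
}

#' Extract the depth-bounded neighbourhood of a vertex
#'
#' Subgraph mode collects the breadth-first reachable set within `depth`
#' edges, keeping each vertex once, with the induced child adjacency. Tree
#' mode fully unfolds to `depth`: a vertex revisited along a different (or
#' cyclic) path is repeated as a fresh occurrence, so the result is a tree
#' rooted at the instance.
#'
#' @param rg a `pgx_reified` graph.
#' @param root node label (original vertex) to root the neighbourhood at.
#' @param cfg a [pgx_kernel_config()] (uses `depth`, `neighborhood`,
#'   `max_occurrences`).
#' @return A `pgx_neighborhood`: `labels` (per occurrence), `adj` (children,
#'   local indices), `root` (local index 1), `mode`.
#' @export
pgx_neighborhood <- function(rg, root, cfg = pgx_kernel_config()) {
  rid <- if (root %in% names(rg$index)) rg$index[[root]] else
    stop("root not in graph: ", root)
  if (cfg$neighborhood == "subgraph") {
    dist <- c(rid)
    seen <- new.env(hash = TRUE)
    assign(as.character(rid), TRUE, envir = seen)
    frontier <- rid; order_v <- rid
    for (d in seq_len(cfg$depth)) {
      nxt <- unique(unlist(rg$adj[frontier], use.names = FALSE))
      if (!length(nxt)) break
      fresh <- nxt[!vapply(as.character(nxt), exists, TRUE, envir = seen,
                           inherits = FALSE)]
      for (v in fresh) assign(as.character(v), TRUE, envir = seen)
      order_v <- c(order_v, sort(fresh))
      frontier <- fresh
      if (!length(frontier)) break
    }
    local <- setNames(seq_along(order_v), order_v)
    adj <- lapply(order_v, function(v) {
      ch <- rg$adj[[v]]
      ch <- ch[as.character(ch) %in% names(local)]
      unname(local[as.character(ch)])
    })
    return(structure(list(labels = rg$labels[order_v], adj = adj, root = 1L,
                          mode = "subgraph", graph_vertex = order_v),
                     class = "pgx_neighborhood"))
  }
  # tree unfolding
  occ_vertex <- rid
  adj <- list(integer())
  frontier <- 1L
  for (d in seq_len(cfg$depth)) {
    children_of <- rg$adj[occ_vertex[frontier]]
    n_new <- sum(lengths(children_of))
    if (n_new == 0L) break
    if (length(occ_vertex) + n_new > cfg$max_occurrences)
      stop("tree unfolding exceeds max_occurrences (",
           format(cfg$max_occurrences, scientific = FALSE),
           ") at depth ", d, " for root ", root)
    new_ids <- length(occ_vertex) + seq_len(n_new)
    occ_vertex <- c(occ_vertex, unlist(children_of, use.names = FALSE))
    pos <- 0L
    for (k in seq_along(frontier)) {
      nk <- length(children_of[[k]])
      adj[[frontier[k]]] <- new_ids[pos + seq_len(nk)]
      pos <- pos + nk
    }
    adj[new_ids] <- list(integer())
    frontier <- new_ids
  }
  structure(list(labels = rg$labels[occ_vertex], adj = adj, root = 1L,
                 mode = "tree", graph_vertex = occ_vertex),
            class = "pgx_neighborhood")
}

#' Count the bag of vertex labels in a neighbourhood
#'
#' @param n a `pgx_neighborhood`.
#' @param min_frequency drop labels whose frequency falls below this.
#' @param global_freq optional named vector of label frequencies over the
#'   whole instance set; when `NULL`, this neighbourhood's own counts are
#'   used as the frequency reference.
#' @return Named numeric vector of label counts (a sparse pattern vector).
#' @export
pgx_count_labels <- function(n, min_frequency = 0, global_freq = NULL) {
  tab <- table(n$labels)
  counts <- setNames(as.numeric(tab), names(tab))
  if (min_frequency > 0) {
    ref <- if (is.null(global_freq)) counts else global_freq
    f <- ref[names(counts)]
    f[is.na(f)] <- 0
    counts <- counts[f >= min_frequency]
  }
  counts
}

#' Count directed-walk label sequences
#'
#' Counts every label sequence realised by a directed walk of `0..l` edges
#' inside the neighbourhood, with multiplicity (number of realisations, not
#' presence). With the root constraint only walks starting at the root
#' occurrence are counted. Length-0 walks are bare vertex labels and are
#' included by default.
#'
#' @param n a `pgx_neighborhood`.
#' @param l maximum walk length (edges).
#' @param root_constraint logical.
#' @param include_zero_length include length-0 walks.
#' @return Named numeric vector: sequence key (labels joined by an
#'   unprintable separator) -> realisation count.
#' @export
pgx_count_walks <- function(n, l, root_constraint = FALSE,
                            include_zero_length = TRUE) {
  stopifnot(l >= 0L)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(keys, by) {
    for (i in seq_along(keys)) {
      k <- keys[i]
      assign(k, (if (exists(k, envir = acc, inherits = FALSE))
        get(k, envir = acc)
        else 0) + by[i], envir = acc)
    }
  }
  starts <- if (root_constraint) n$root else seq_along(n$labels)
  # state: end vertex, sequence key, count (aggregated)
  st_end <- starts
  st_key <- n$labels[starts]
  st_cnt <- rep(1, length(starts))
  if (include_zero_length) {
    agg <- tapply(st_cnt, st_key, sum)
    bump(names(agg), as.numeric(agg))
  }
  len <- 0L
  while (len < l && length(st_end)) {
    ch <- n$adj[st_end]
    reps <- lengths(ch)
    if (sum(reps) == 0L) break
    new_end <- unlist(ch, use.names = FALSE)
    new_key <- paste0(rep(st_key, reps), SEQ_SEP, n$labels[new_end])
    new_cnt <- rep(st_cnt, reps)
    # aggregate identical (end, key) states
    gk <- paste0(new_end, SEQ_SEP, new_key)
    agg <- rowsum(new_cnt, gk, reorder = FALSE)
    first <- !duplicated(gk)
    st_end <- new_end[first]
    st_key <- new_key[first]
    st_cnt <- as.numeric(agg[match(gk[first], rownames(agg)), 1L])
    byseq <- tapply(st_cnt, st_key, sum)
    bump(names(byseq), as.numeric(byseq))
    len <- len + 1L
  }
  keys <- ls(acc, sorted = TRUE)
  setNames(vapply(keys, get, 0, envir = acc), keys)
}

#' Count iteratively refined subtree patterns
#'
#' Weisfeiler-Lehman style refinement: at iteration 0 every occurrence's
#' refined label is its own label; at iteration `h` it is the canonical
#' string of its previous refined label and the sorted multiset of its
#' children's refined labels at `h - 1`. All refined labels at iterations
#' `0..depth` are counted (root occurrence only under the root constraint).
#' Canonical strings are globally comparable across neighbourhoods, so the
#' resulting sparse vectors feed directly into a kernel.
#'
#' @param n a `pgx_neighborhood`.
#' @param depth maximum refinement depth.
#' @param root_constraint logical.
#' @return Named numeric vector: canonical pattern -> count.
#' @export
pgx_count_subtrees <- function(n, depth, root_constraint = FALSE) {
  stopifnot(depth >= 0L)
  nv <- length(n$labels)
  refined <- n$labels
  counted <- if (root_constraint) n$root else seq_len(nv)
  acc <- list()
  collect <- function(lv) {
    tab <- tapply(rep(1, length(counted)), refined[counted], sum)
    acc[[length(acc) + 1L]] <<- tab
  }
  collect(0L)
  h <- 0L
  while (h < depth) {
    refined <- vapply(seq_len(nv), function(v) {
      ch <- n$adj[[v]]
      paste0(refined[v], "(",
             paste(sort(refined[ch]), collapse = ","), ")")
    }, "")
    collect(h + 1L)
    h <- h + 1L
  }
  all <- unlist(acc)
  out <- tapply(as.numeric(all), names(all), sum)
  setNames(as.numeric(out), names(out))
}

#' Apply a global minimum-frequency filter to pattern vectors
#'
#' Drops every pattern whose total count over the instance set falls below
#' `min_frequency`. Applied uniformly so kernel comparability is preserved;
#' `min_frequency = 0` is the identity.
#'
#' @param counts_list list of named pattern-count vectors.
#' @param min_frequency threshold on the global count.
#' @return The filtered list.
#' @export
pgx_filter_min_frequency <- function(counts_list, min_frequency) {
  if (min_frequency <= 0) return(counts_list)
  all <- unlist(counts_list)
  tot <- tapply(as.numeric(all), names(all), sum)
  keep <- names(tot)[tot >= min_frequency]
  lapply(counts_list, function(v) v[names(v) %in% keep])
}

#' Sparse dot-product kernel matrix
#'
#' `K[i, j]` is the dot product of the instances' sparse pattern-count
#' vectors; with `normalize`, cosine normalisation is applied (all-zero
#' vectors yield 0). The result is symmetric and positive semidefinite by
#' construction.
#'
#' @param counts_list non-empty list of named pattern-count vectors.
#' @param normalize logical.
#' @return A dense symmetric numeric matrix.
#' @export
pgx_kernel_matrix <- function(counts_list, normalize = TRUE) {
  if (!length(counts_list)) stop("empty list of count vectors")
  patterns <- unique(unlist(lapply(counts_list, names), use.names = FALSE))
  ni <- lengths(counts_list)
  if (!length(patterns)) {
    K <- matrix(0, length(counts_list), length(counts_list))
  } else {
    X <- Matrix::sparseMatrix(
      i = rep(seq_along(counts_list), ni),
      j = match(unlist(lapply(counts_list, names), use.names = FALSE),
                patterns),
      x = as.numeric(unlist(counts_list, use.names = FALSE)),
      dims = c(length(counts_list), length(patterns)))
    K <- as.matrix(Matrix::tcrossprod(X))
  }
  if (normalize) {
    d <- sqrt(diag(K))
    scale <- outer(d, d)
    K <- ifelse(scale > 0, K / scale, 0)
    diag(K)[d > 0] <- 1
  }
  unname(K)
}

#' Compute the pair-node kernel for a graph
#'
#' High-level kernel route: strips class-membership edges (so training
#' labels never leak into neighbourhoods), reifies the graph, extracts each
#' pair node's neighbourhood, counts the configured substructures, applies
#' the global minimum-frequency filter, and returns the kernel matrix.
#'
#' @param g a `pgx_graph` containing pair nodes (directions already
#'   normalised as desired).
#' @param pair_labels character vector of pair-node labels (rows/columns of
#'   the kernel, in this order).
#' @param cfg a [pgx_kernel_config()].
#' @return list with `K` (kernel matrix), `counts` (pattern vectors per
#'   pair).
#' @export
pgx_pair_kernel <- function(g, pair_labels, cfg = pgx_kernel_config()) {
  g$edges <- g$edges[g$edges$predicate != PX_IS_A, , drop = FALSE]
  cls <- g$nodes$label[g$nodes$type == "ClassNode"]
  g$nodes <- g$nodes[!(g$nodes$label %in% cls), , drop = FALSE]
  rg <- pgx_reify(g)
  counts <- lapply(pair_labels, function(p) {
    nb <- pgx_neighborhood(rg, p, cfg)
    switch(cfg$substructure,
           bag_of_labels = pgx_count_labels(nb),
           walks = pgx_count_walks(nb, cfg$substructure_size,
                                   cfg$root_constraint,
                                   cfg$include_zero_length_walks),
           subtrees = pgx_count_subtrees(nb, cfg$substructure_size,
                                         cfg$root_constraint))
  })
  counts <- pgx_filter_min_frequency(counts, cfg$min_frequency)
  list(K = pgx_kernel_matrix(counts, cfg$normalize), counts = counts)
}
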