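# Multi-instance path-feature formatting: one categorical row per combination
# of length-1 paths and attributes around a gene-drug pair, one-hot encoding
# with a frozen training vocabulary, information-gain feature filtering.

NA_TOKEN <- "NA"

FEATURE_SLOTS <- c("gene_attribute", "phenotype", "drug_attribute",
                   "gd_link", "gp_link", "dp_link")

#' Slot-extraction configuration for path features
#'
#' @param include_disease_attribute include the optional phenotype-attribute
#'   slot (MeSH-class-like); off by default, as it carries little information
#'   and is routinely filtered out by information gain.
#' @param traverse_mappings read slot values from a pair's entity and all its
#'   declared equivalents (attributes are often spread across provenance
#'   nodes).
#' @return A configuration list.
#' @export
pgx_feature_config <- function(include_disease_attribute = FALSE,
                               traverse_mappings = TRUE) {
  list(include_disease_attribute = include_disease_attribute,
       traverse_mappings = traverse_mappings)
}

# Precompute adjacency and equivalence-closure indexes for fast slot lookups.
feature_index <- function(g, cfg) {
  e <- g$edges[g$edges$predicate != PX_MAPPED_TO, , drop = FALSE]
  type <- setNames(g$nodes$type, g$nodes$label)
  canon <- if (cfg$traverse_mappings && nrow(g$mappings))
    equivalence_canonical(g$nodes$label, g$mappings)
  else setNames(g$nodes$label, g$nodes$label)
  members <- split(names(canon), unname(canon))
  by_subject <- split(seq_len(nrow(e)), e$subject)
  list(edges = e, type = type, canon = canon, members = members,
       by_subject = by_subject)
}

slot_or_na <- function(x) if (length(x)) sort(unique(x)) else NA_TOKEN

# Enumerate the categorical instance rows for one pair against a prebuilt
# index. Returns a data.frame in the Table-1-like column layout.
build_instances_indexed <- function(idx, gene, drug, class_value, cfg,
                                    pair_id) {
  eq_set <- function(label) {
    cn <- idx$canon[[label]]
    if (is.null(cn)) label else idx$members[[cn]]
  }
  out_edges <- function(labels) {
    rows <- unlist(idx$by_subject[labels], use.names = FALSE)
    idx$edges[rows, , drop = FALSE]
  }
  genes <- eq_set(gene); drugs <- eq_set(drug)
  ge <- out_edges(genes); de <- out_edges(drugs)
  g_types <- idx$type[ge$object]; d_types <- idx$type[de$object]

  gene_attr <- slot_or_na(ge$object[g_types == "AttributeValue"])
  drug_attr <- slot_or_na(de$object[d_types == "AttributeValue"])
  gd_link <- slot_or_na(c(ge$predicate[ge$object %in% drugs],
                          de$predicate[de$object %in% genes]))

  # shared phenotypes, resolved through equivalence classes
  gp <- ge[g_types == "Phenotype", , drop = FALSE]
  dp <- de[d_types == "Phenotype", , drop = FALSE]
  gp_canon <- unname(idx$canon[gp$object])
  dp_canon <- unname(idx$canon[dp$object])
  shared <- sort(intersect(gp_canon, dp_canon))
  if (length(shared)) {
    trip <- do.call(rbind, lapply(shared, function(ph) {
      gpp <- sort(unique(gp$predicate[gp_canon == ph]))
      dpp <- sort(unique(dp$predicate[dp_canon == ph]))
      expand.grid(gp_link = gpp, dp_link = dpp, phenotype = ph,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
  } else {
    trip <- data.frame(gp_link = NA_TOKEN, dp_link = NA_TOKEN,
                       phenotype = NA_TOKEN)
  }
  grid <- expand.grid(gene_attribute = gene_attr,
                      drug_attribute = drug_attr,
                      gd_link = gd_link,
                      trip_row = seq_len(nrow(trip)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- data.frame(pair_id = pair_id,
                     gene_attribute = grid$gene_attribute,
                     phenotype = trip$phenotype[grid$trip_row],
                     drug_attribute = grid$drug_attribute,
                     gd_link = grid$gd_link,
                     gp_link = trip$gp_link[grid$trip_row],
                     dp_link = trip$dp_link[grid$trip_row])
  if (isTRUE(cfg$include_disease_attribute)) {
    ph_set <- unlist(idx$members[shared], use.names = FALSE)
    pe <- out_edges(ph_set)
    dis <- slot_or_na(pe$object[idx$type[pe$object] == "AttributeValue"])
    rows <- merge(rows, data.frame(disease_attribute = dis), by = NULL)
  }
  rows$class <- class_value
  ord <- do.call(order, rows[setdiff(names(rows), c("pair_id", "class"))])
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Enumerate the instance bag of one gene--drug pair
#'
#' A pair is described by several categorical rows (a multi-instance bag):
#' one row per combination of gene attribute, drug attribute, direct
#' gene--drug link, and -- for every phenotype reachable from the gene via one
#' gene--phenotype edge and from the drug via one drug--phenotype edge -- the
#' (gene-phenotype predicate, phenotype, drug-phenotype predicate) triple.
#' Any slot with no values contributes the single reserved token `"NA"`; an
#' isolated pair yields one all-NA row. Slot values are read from the pair's
#' entities and their declared equivalents.
#'
#' @param g a `pgx_graph`.
#' @param pair one-row data.frame with `gene`, `drug` and optionally `label`.
#' @param cfg a [pgx_feature_config()].
#' @return data.frame of instance rows (`pair_id`, the six slot columns,
#'   `class`).
#' @export
pgx_build_instances <- function(g, pair, cfg = pgx_feature_config()) {
  pgx_build_bags(g, pair, cfg)
}

#' Enumerate instance bags for a table of pairs
#'
#' @param g a `pgx_graph`.
#' @param pairs data.frame with `gene`, `drug`, optional `label`.
#' @param cfg a [pgx_feature_config()].
#' @param on_missing `"error"` (default) fails when a pair's gene or drug is
#'   absent from the graph; `"na"` scores such pairs with a single all-NA row
#'   and a warning (used for test candidates).
#' @return data.frame of instance rows for all pairs; each row belongs to
#'   exactly one pair.
#' @export
pgx_build_bags <- function(g, pairs, cfg = pgx_feature_config(),
                           on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(pair_id = character()))
  if (!"label" %in% names(pairs)) pairs$label <- "unknown"
  idx <- feature_index(g, cfg)
  class_value <- ifelse(pairs$label == "associated", "1",
                        ifelse(pairs$label == "not_associated", "0",
                               "unknown"))
  pair_id <- paste(pairs$gene, pairs$drug, sep = "|")
  missing <- !(pairs$gene %in% g$nodes$label) |
             !(pairs$drug %in% g$nodes$label)
  if (any(missing)) {
    if (on_missing == "error")
      stop("pair(s) reference absent gene or drug: ",
           paste(head(pair_id[missing], 5L), collapse = ", "))
    warning(sum(missing), " pair(s) absent from graph scored all-NA")
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (missing[i]) {
      row <- data.frame(pair_id = pair_id[i], gene_attribute = NA_TOKEN,
                        phenotype = NA_TOKEN, drug_attribute = NA_TOKEN,
                        gd_link = NA_TOKEN, gp_link = NA_TOKEN,
                        dp_link = NA_TOKEN)
      if (isTRUE(cfg$include_disease_attribute))
        row$disease_attribute <- NA_TOKEN
      row$class <- class_value[i]
      out[[i]] <- row
    } else {
      out[[i]] <- build_instances_indexed(idx, pairs$gene[i], pairs$drug[i],
                                          class_value[i], cfg, pair_id[i])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-hot encode instance rows into a sparse feature matrix
#'
#' Builds (or reuses) a per-slot vocabulary and encodes each categorical slot
#' as one-hot columns named `slot=value`. Every slot includes an `NA` level;
#' at test time, values unseen in the frozen training vocabulary map to the
#' slot's NA column, so train and test matrices share columns.
#'
#' @param rows instance rows from [pgx_build_bags()].
#' @param vocab optional frozen vocabulary (from a training-time matrix's
#'   `$vocab`); `NULL` builds it from `rows`.
#' @return A `pgx_feature_matrix`: list with `rows`, `slots`, `vocab`, sparse
#'   matrix `X` (`dgCMatrix`), class vector `y` (`"1"`, `"0"`, `"unknown"`),
#'   `pair_id`.
#' @export
pgx_build_matrix <- function(rows, vocab = NULL) {
  slots <- setdiff(names(rows), c("pair_id", "class"))
  if (is.null(vocab))
    vocab <- lapply(setNames(slots, slots), function(s)
      sort(unique(c(NA_TOKEN, rows[[s]]))))
  else
    slots <- names(vocab)
  n <- nrow(rows)
  offsets <- c(0L, cumsum(vapply(vocab, length, 0L)))
  ncols <- offsets[length(offsets)]
  cn <- unlist(lapply(seq_along(slots),
                      function(k) paste0(slots[k], "=", vocab[[k]])))
  if (n == 0L || length(slots) == 0L) {
    X <- Matrix::Matrix(0, nrow = n, ncol = ncols, sparse = TRUE,
                        dimnames = list(NULL, cn))
  } else {
    ii <- jj <- vector("list", length(slots))
    for (k in seq_along(slots)) {
      v <- rows[[slots[k]]]
      pos <- match(v, vocab[[k]])
      pos[is.na(pos)] <- match(NA_TOKEN, vocab[[k]])
      ii[[k]] <- seq_len(n)
      jj[[k]] <- offsets[k] + pos
    }
    X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                              dims = c(n, ncols), dimnames = list(NULL, cn))
  }
  structure(list(rows = rows, slots = slots, vocab = vocab, X = X,
                 y = if (n && "class" %in% names(rows)) rows$class
                     else character(),
                 pair_id = if (n) rows$pair_id else character()),
            class = "pgx_feature_matrix")
}

#' @method print pgx_feature_matrix
#' @export
print.pgx_feature_matrix <- function(x, ...) {
  cat("<pgx_feature_matrix> ", nrow(x$X), " instances x ", ncol(x$X),
      " one-hot columns (", length(x$slots), " slots)\n", sep = "")
  invisible(x)
}

#' Decode a one-hot feature matrix back to categorical rows
#'
#' @param m a `pgx_feature_matrix`.
#' @return data.frame of categorical slot values (round-trip of the encoding).
#' @export
pgx_decode_matrix <- function(m) {
  out <- data.frame(pair_id = m$pair_id)
  offsets <- c(0L, cumsum(vapply(m$vocab, length, 0L)))
  Xd <- as.matrix(m$X)
  for (k in seq_along(m$slots)) {
    block <- Xd[, (offsets[k] + 1L):offsets[k + 1L], drop = FALSE]
    out[[m$slots[k]]] <- m$vocab[[k]][max.col(block, ties.method = "first")]
  }
  out$class <- m$y
  out
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a categorical slot with respect to the class
#'
#' Computes `H(class) - H(class | slot)` in bits on the labelled rows
#' (classes `"1"` and `"0"`), using the categorical slot values before
#' one-hot encoding.
#'
#' @param m a `pgx_feature_matrix`.
#' @param slot slot name (e.g. `"phenotype"`).
#' @return Non-negative gain in bits, at most `H(class)`.
#' @export
pgx_information_gain <- function(m, slot) {
  if (!slot %in% m$slots) stop("unknown slot: ", slot)
  lab <- m$y %in% c("0", "1")
  y <- m$y[lab]; v <- m$rows[[slot]][lab]
  if (!length(y)) stop("no labelled rows")
  h <- entropy_bits(y)
  cond <- sum(vapply(split(y, v), function(ys)
    length(ys) / length(y) * entropy_bits(ys), 0))
  max(0, h - cond)
}

#' Drop uninformative slots by information gain
#'
#' Every slot whose information gain falls below `threshold` is removed from
#' the rows and the encoding (training and any matrix later encoded with the
#' returned vocabulary). Dropped slots and their gains are recorded in the
#' `dropped` attribute.
#'
#' @param m a `pgx_feature_matrix` with labelled rows.
#' @param threshold minimum gain in bits (`0` keeps everything).
#' @return A re-encoded `pgx_feature_matrix` on the surviving slots.
#' @export
pgx_filter_features <- function(m, threshold) {
  stopifnot(threshold >= 0)
  gains <- vapply(m$slots, function(s) pgx_information_gain(m, s), 0)
  keep <- gains >= threshold
  if (!any(keep)) stop("information-gain threshold ", threshold,
                       " would drop every slot")
  rows <- m$rows[, c("pair_id", m$slots[keep], "class"), drop = FALSE]
  out <- pgx_build_matrix(rows, vocab = m$vocab[keep])
  attr(out, "dropped") <- gains[!keep]
  attr(out, "gains") <- gains
  out
}
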