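#' @importFrom stats aggregate predict glm binomial rpois rbinom runif setNames
#' @importFrom utils head read.delim write.table combn
NULL

# Node types recognised by the pharmacogenomic graph schema.
PGX_NODE_TYPES <- c("Gene", "Drug", "Phenotype", "GeneDrugPairNode",
                    "AttributeValue", "ClassNode", "Generic")

# Reserved vocabulary predicates (px namespace).
PX_MAPPED_TO <- "px:mapped_to"
PX_HAS_GENE  <- "px:has_gene"
PX_HAS_DRUG  <- "px:has_drug"
PX_IS_A      <- "px:is_a"
CLASS_POS    <- "class:associated"
CLASS_NEG    <- "class:not_associated"

#' Construct a typed pharmacogenomic linked-data graph
#'
#' A `pgx_graph` is a directed, edge-labeled multigraph over typed entities:
#' genes, drugs, phenotypes, attribute values (pathway memberships, ATC
#' codes), gene--drug pair nodes and the two class nodes used to label
#' training pairs. Node labels are compact `namespace:local_id` strings;
#' rendering is injective and comparison is exact string equality.
#'
#' @param nodes data.frame with columns `label`, `type` (one of
#'   `r paste(PGX_NODE_TYPES, collapse = ", ")`).
#' @param edges data.frame with columns `subject`, `predicate`, `object`;
#'   a multiset (duplicate rows are distinct edge occurrences).
#' @param mappings data.frame with columns `left`, `right`, `method`
#'   recording declared cross-source equivalences between same-type nodes.
#' @return An object of class `pgx_graph`.
#' @export
pgx_graph <- function(nodes = NULL, edges = NULL, mappings = NULL) {
  if (is.null(nodes))
    nodes <- data.frame(label = character(), type = character())
  if (is.null(edges))
    edges <- data.frame(subject = character(), predicate = character(),
                        object = character())
  if (is.null(mappings))
    mappings <- data.frame(left = character(), right = character(),
                           method = character())
  nodes <- as.data.frame(nodes)[, c("label", "type")]
  edges <- as.data.frame(edges)[, c("subject", "predicate", "object")]
  mappings <- as.data.frame(mappings)[, c("left", "right", "method")]
  rownames(nodes) <- rownames(edges) <- rownames(mappings) <- NULL
  g <- structure(list(nodes = nodes, edges = edges, mappings = mappings),
                 class = "pgx_graph")
  validate_pgx_graph(g)
  g
}

validate_pgx_graph <- function(g) {
  if (anyDuplicated(g$nodes$label))
    stop("duplicate node labels: ",
         paste(unique(g$nodes$label[duplicated(g$nodes$label)]), collapse = ", "))
  bad <- setdiff(g$nodes$type, PGX_NODE_TYPES)
  if (length(bad)) stop("unknown node types: ", paste(bad, collapse = ", "))
  ep <- unique(c(g$edges$subject, g$edges$object))
  missing <- setdiff(ep, g$nodes$label)
  if (length(missing))
    stop("edge endpoints absent from node set: ",
         paste(head(missing, 5), collapse = ", "))
  if (nrow(g$mappings)) {
    tt <- node_types(g, g$mappings$left) == node_types(g, g$mappings$right)
    if (!all(tt)) stop("mappings must connect nodes of the same type")
  }
  invisible(g)
}

node_types <- function(g, labels) {
  g$nodes$type[match(labels, g$nodes$label)]
}

#' @method print pgx_graph
#' @export
print.pgx_graph <- function(x, ...) {
  cat("<pgx_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges, ",
      nrow(x$mappings), " mappings\n", sep = "")
  if (nrow(x$nodes)) print(table(x$nodes$type))
  invisible(x)
}

#' Default namespace schema for the pharmacogenomic graph
#'
#' Maps each namespace to its node type and its URI prefix (used when
#' serialising to and from N-Triples). Two namespaces per entity type mimic
#' multi-source provenance (e.g. a ClinVar-like and a DisGeNET-like gene
#' namespace) joined by equivalence mappings.
#'
#' @return data.frame with columns `namespace`, `type`, `uri_prefix`.
#' @export
pgx_default_schema <- function() {
  data.frame(
    namespace = c("gena", "genb", "druga", "drugb", "phena", "phenb",
                  "pw", "atc", "class", "pair"),
    type = c("Gene", "Gene", "Drug", "Drug", "Phenotype", "Phenotype",
             "AttributeValue", "AttributeValue", "ClassNode",
             "GeneDrugPairNode"),
    uri_prefix = paste0("http://pgx.example.org/",
                        c("gena", "genb", "druga", "drugb", "phena", "phenb",
                          "pathway", "atc", "class", "pair"), "/")
  )
}

PX_URI_PREFIX <- "http://pgx.example.org/vocab/"
TAG_PREFIX <- "tag:pgx,"
RDF_TYPE_URI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

label_namespace <- function(label) sub(":.*$", "", label)
label_local <- function(label) sub("^[^:]*:", "", label)

uri_to_label <- function(uri, schema) {
  if (startsWith(uri, TAG_PREFIX)) return(substring(uri, nchar(TAG_PREFIX) + 1L))
  if (startsWith(uri, PX_URI_PREFIX))
    return(paste0("px:", substring(uri, nchar(PX_URI_PREFIX) + 1L)))
  hit <- which(startsWith(uri, schema$uri_prefix))
  if (length(hit)) {
    i <- hit[which.max(nchar(schema$uri_prefix[hit]))]
    return(paste0(schema$namespace[i],
                  ":", substring(uri, nchar(schema$uri_prefix[i]) + 1L)))
  }
  uri
}

label_to_uri <- function(label, schema) {
  ns <- label_namespace(label)
  if (ns == "px") return(paste0(PX_URI_PREFIX, label_local(label)))
  i <- match(ns, schema$namespace)
  if (!is.na(i)) return(paste0(schema$uri_prefix[i], label_local(label)))
  if (grepl("^[a-z][a-z0-9+.-]*://", label)) return(label)
  paste0(TAG_PREFIX, label)
}

# --- triple file parsing ----------------------------------------------------

# Tokenise one RDF statement line into resource/literal terms. Handles
# <uri>, prefixed names, and double-quoted literals (with \" escapes).
tokenize_turtle <- function(text) {
  toks <- list(); types <- character()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "<") {
      j <- regexpr(">", substring(text, i))
      if (j < 0) stop("unterminated IRI in: ", text)
      toks[[length(toks) + 1L]] <- substr(text, i + 1L, i + j - 2L)
      types <- c(types, "iri"); i <- i + j; next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == "\"") break
        j <- j + 1L
      }
      if (j > n) stop("unterminated literal in: ", text)
      lit <- substr(text, i + 1L, j - 1L)
      lit <- gsub("\\\\(.)", "\\1", lit)
      i <- j + 1L
      # skip datatype / language tags
      rest <- substring(text, i)
      m <- regexpr("^(\\^\\^<[^>]*>|\\^\\^[A-Za-z0-9_.:-]+|@[A-Za-z-]+)", rest)
      if (m > 0) i <- i + attr(m, "match.length")
      toks[[length(toks) + 1L]] <- lit
      types <- c(types, "literal"); next
    }
    if (ch %in% c(".", ";", ",")) {
      toks[[length(toks) + 1L]] <- ch
      types <- c(types, "punct"); i <- i + 1L; next
    }
    # bare token (prefixed name, @prefix keyword, blank node)
    m <- regexpr("^[^\\s<\"#;,]+", substring(text, i), perl = TRUE)
    tok <- regmatches(substring(text, i), m)
    # a bare token may end in the statement terminator
    if (grepl("\\.$", tok) && tok != "." && !grepl("^[0-9]", tok)) {
      tok2 <- sub("\\.$", "", tok)
      toks[[length(toks) + 1L]] <- tok2; types <- c(types, "name")
      toks[[length(toks) + 1L]] <- "."; types <- c(types, "punct")
    } else {
      toks[[length(toks) + 1L]] <- tok; types <- c(types, "name")
    }
    i <- i + attr(m, "match.length")
  }
  list(tokens = unlist(toks), types = types)
}

# Parse N-Triples or a prefixed-Turtle subset (@prefix, ';' and ','
# continuations). Blank nodes are rejected: the schema has no use for them.
parse_triple_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  prefixes <- character()
  subj <- character(); pred <- character(); obj <- character()
  is_lit <- logical()
  cur_s <- NULL; cur_p <- NULL
  expand <- function(tok, type, lineno) {
    if (type == "iri") return(list(v = tok, lit = FALSE))
    if (type == "literal") return(list(v = tok, lit = TRUE))
    if (tok == "a") return(list(v = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
                                lit = FALSE))
    if (startsWith(tok, "_:"))
      stop(path, ":", lineno, ": blank nodes are not supported")
    pfx <- sub(":.*$", "", tok)
    if (!grepl(":", tok) || !(pfx %in% names(prefixes)))
      stop(path, ":", lineno, ": undeclared prefix in token '", tok, "'")
    list(v = paste0(prefixes[[pfx]], sub("^[^:]*:", "", tok)), lit = FALSE)
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    tk <- tryCatch(tokenize_turtle(line),
                   error = function(e) stop(path, ":", ln, ": ",
                                            conditionMessage(e), call. = FALSE))
    tokens <- tk$tokens; types <- tk$types
    if (!length(tokens)) next
    if (tokens[1] %in% c("@prefix", "PREFIX", "prefix")) {
      if (length(tokens) < 3L)
        stop(path, ":", ln, ": malformed prefix declaration")
      prefixes[[sub(":$", "", tokens[2])]] <- tokens[3]
      next
    }
    k <- 1L
    while (k <= length(tokens)) {
      tok <- tokens[k]; ty <- types[k]
      if (ty == "punct") {
        if (tok == ".") { cur_s <- NULL; cur_p <- NULL }
        k <- k + 1L; next
      }
      if (is.null(cur_s)) {
        term <- expand(tok, ty, ln)
        if (term$lit) stop(path, ":", ln, ": literal in subject position")
        cur_s <- term$v; k <- k + 1L; next
      }
      if (is.null(cur_p)) {
        term <- expand(tok, ty, ln)
        if (term$lit) stop(path, ":", ln, ": literal in predicate position")
        cur_p <- term$v; k <- k + 1L; next
      }
      term <- expand(tok, ty, ln)
      subj <- c(subj, cur_s); pred <- c(pred, cur_p)
      obj <- c(obj, term$v); is_lit <- c(is_lit, term$lit)
      k <- k + 1L
      # lookahead: ',' keeps subject+predicate, ';' keeps subject
      if (k <= length(tokens) && types[k] == "punct") {
        if (tokens[k] == ",") { k <- k + 1L; next }
        if (tokens[k] == ";") { cur_p <- NULL; k <- k + 1L; next }
      }
      if (k <= length(tokens) && types[k] != "punct") cur_p <- NULL
    }
  }
  data.frame(subject = subj, predicate = pred, object = obj,
             object_is_literal = is_lit)
}

#' Load a pharmacogenomic graph from triple files
#'
#' Reads N-Triples (and a prefixed-Turtle subset) files, converts URIs to
#' compact labels using the schema's namespace prefixes, and types every node
#' by its namespace. Literal objects become `AttributeValue` nodes (labelled
#' `lit:<value>`) so that downstream kernels can count them as labels.
#' Mapping triples (predicate `px:mapped_to`) additionally populate the
#' graph's mapping table.
#'
#' @param paths character vector of `.nt`/`.ttl` file paths.
#' @param schema namespace schema, as from [pgx_default_schema()].
#' @return A `pgx_graph` with a `load_report` attribute (JSON-serialisable
#'   list of node counts per type, untyped node count, edge count).
#' @export
pgx_load_graph <- function(paths, schema = pgx_default_schema()) {
  tr <- do.call(rbind, lapply(paths, parse_triple_file))
  if (is.null(tr) || nrow(tr) == 0L) {
    g <- pgx_graph()
    attr(g, "load_report") <- list(n_nodes = 0L, n_edges = 0L,
                                   nodes_by_type = list(), untyped_nodes = 0L,
                                   files = as.character(paths))
    return(g)
  }
  decl <- tr$predicate == RDF_TYPE_URI & !tr$object_is_literal &
    startsWith(tr$object, paste0(TAG_PREFIX, "nodetype:"))
  decl_nodes <- data.frame(
    label = vapply(tr$subject[decl], uri_to_label, "", schema = schema,
                   USE.NAMES = FALSE),
    type = sub(paste0("^", TAG_PREFIX, "nodetype:"), "", tr$object[decl]))
  tr <- tr[!decl, , drop = FALSE]
  if (nrow(tr) == 0L && nrow(decl_nodes) == 0L) {
    g <- pgx_graph()
    attr(g, "load_report") <- list(n_nodes = 0L, n_edges = 0L,
                                   nodes_by_type = list(), untyped_nodes = 0L,
                                   files = as.character(paths))
    return(g)
  }
  s_lab <- vapply(tr$subject, uri_to_label, "", schema = schema,
                  USE.NAMES = FALSE)
  p_lab <- vapply(tr$predicate, uri_to_label, "", schema = schema,
                  USE.NAMES = FALSE)
  o_lab <- ifelse(tr$object_is_literal, paste0("lit:", tr$object),
                  vapply(tr$object, uri_to_label, "", schema = schema,
                         USE.NAMES = FALSE))
  labs <- unique(c(s_lab, o_lab, decl_nodes$label))
  ns <- vapply(labs, label_namespace, "", USE.NAMES = FALSE)
  type <- schema$type[match(ns, schema$namespace)]
  type[ns == "lit"] <- "AttributeValue"
  di <- match(labs, decl_nodes$label)
  type[!is.na(di)] <- decl_nodes$type[di[!is.na(di)]]
  untyped <- sum(is.na(type))
  if (untyped > 0L)
    warning(untyped, " node(s) in undeclared namespaces kept with generic type")
  type[is.na(type)] <- "Generic"
  nodes <- data.frame(label = labs, type = type)
  edges <- data.frame(subject = s_lab, predicate = p_lab, object = o_lab)
  map_rows <- edges$predicate == PX_MAPPED_TO
  mappings <- if (any(map_rows)) {
    mm <- edges[map_rows, c("subject", "object")]
    lr <- t(apply(mm, 1L, sort))
    mm <- unique(data.frame(left = lr[, 1L], right = lr[, 2L],
                            method = "declared"))
    mm
  } else NULL
  g <- pgx_graph(nodes, edges, mappings)
  tab <- table(nodes$type)
  attr(g, "load_report") <- list(
    n_nodes = nrow(nodes), n_edges = nrow(edges),
    nodes_by_type = as.list(setNames(as.integer(tab), names(tab))),
    untyped_nodes = untyped, n_mappings = nrow(g$mappings),
    files = as.character(paths))
  g
}

#' Write a graph to N-Triples
#'
#' Inverse of [pgx_load_graph()]: node labels with schema-known namespaces
#' expand to their URI prefixes; other labels round-trip through a `tag:` URI.
#' Output line order is deterministic (edge order as stored).
#'
#' @param g a `pgx_graph`.
#' @param path output file path.
#' @param schema namespace schema used for URI expansion.
#' @return `path`, invisibly.
#' @export
pgx_write_graph <- function(g, path, schema = pgx_default_schema()) {
  e <- g$edges
  lit <- startsWith(e$object, "lit:")
  s <- vapply(e$subject, label_to_uri, "", schema = schema, USE.NAMES = FALSE)
  p <- vapply(e$predicate, label_to_uri, "", schema = schema, USE.NAMES = FALSE)
  o <- character(nrow(e))
  o[!lit] <- paste0("<", vapply(e$object[!lit], label_to_uri, "",
                                schema = schema, USE.NAMES = FALSE), ">")
  o[lit] <- paste0("\"", gsub("\"", "\\\\\"", substring(e$object[lit], 5L)), "\"")
  lines <- paste0("<", s, "> <", p, "> ", o, " .")
  # isolated nodes leave no edge trace; declare them with rdf:type so a
  # round trip reproduces the node set
  iso <- !(g$nodes$label %in% c(e$subject, e$object))
  if (any(iso)) {
    iso_s <- vapply(g$nodes$label[iso], label_to_uri, "", schema = schema,
                    USE.NAMES = FALSE)
    lines <- c(lines, paste0(
      "<", iso_s, "> <", RDF_TYPE_URI, "> <", TAG_PREFIX, "nodetype:",
      g$nodes$type[iso], "> ."))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --- equivalence mappings ---------------------------------------------------

#' Infer cross-source equivalence mappings from shared identifiers
#'
#' Applies per-namespace regular expressions (one capture group each) to node
#' local identifiers; two same-type nodes from different namespaces whose
#' extracted identifiers are string-equal are declared equivalent. This
#' mirrors identifier-based entity resolution across linked-data sources
#' (e.g. a shared NCBI gene id or UMLS CUI appearing under two namespaces).
#'
#' @param g a `pgx_graph`.
#' @param extractors named character vector: namespace -> regex with exactly
#'   one capture group, applied to the local part of each label.
#' @return data.frame of mappings (`left`, `right`, `method =
#'   "shared_identifier"`), sorted, with `left < right`.
#' @export
pgx_infer_mappings <- function(g, extractors) {
  out <- data.frame(left = character(), right = character(),
                    method = character())
  if (!nrow(g$nodes) || !length(extractors)) return(out)
  ns <- vapply(g$nodes$label, label_namespace, "", USE.NAMES = FALSE)
  keys <- rep(NA_character_, nrow(g$nodes))
  for (nsi in names(extractors)) {
    idx <- which(ns == nsi)
    if (!length(idx)) {
      warning("extractor for namespace '", nsi, "' matched 0 nodes")
      next
    }
    loc <- label_local(g$nodes$label[idx])
    m <- regexec(extractors[[nsi]], loc)
    got <- vapply(regmatches(loc, m),
                  function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")
    if (all(is.na(got)))
      warning("extractor for namespace '", nsi, "' matched 0 nodes")
    keys[idx] <- got
  }
  ok <- which(!is.na(keys))
  if (!length(ok)) return(out)
  grp <- split(ok, paste(g$nodes$type[ok], keys[ok], sep = "\r"))
  res <- list()
  for (ix in grp) {
    if (length(ix) < 2L) next
    cross <- combn(ix, 2L)
    for (j in seq_len(ncol(cross))) {
      a <- cross[1L, j]; b <- cross[2L, j]
      if (ns[a] == ns[b]) next
      lr <- sort(c(g$nodes$label[a], g$nodes$label[b]))
      res[[length(res) + 1L]] <- lr
    }
  }
  if (!length(res)) return(out)
  mm <- unique(data.frame(left = vapply(res, `[`, "", 1L),
                          right = vapply(res, `[`, "", 2L),
                          method = "shared_identifier"))
  mm <- mm[order(mm$left, mm$right), ]
  rownames(mm) <- NULL
  mm
}

# Union-find over labels; returns named vector label -> canonical label
# (lexicographically smallest member of each equivalence class).
equivalence_canonical <- function(labels, mappings) {
  parent <- setNames(seq_along(labels), labels)
  find <- function(i) { while (parent[[i]] != i) { parent[[i]] <<- parent[[parent[[i]]]]; i <- parent[[i]] }; i }
  if (nrow(mappings)) for (k in seq_len(nrow(mappings))) {
    a <- find(match(mappings$left[k], labels))
    b <- find(match(mappings$right[k], labels))
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(seq_along(labels), find, 0L)
  canon <- vapply(split(seq_along(labels), roots),
                  function(ix) min(labels[ix]), "")
  setNames(canon[as.character(roots)], labels)
}

#' Merge equivalent entities
#'
#' Two modes. `edge` (default) materialises each mapping as a pair of
#' directed `px:mapped_to` edges, preserving provenance: kernel walks may
#' traverse the mapping while both source nodes keep their own attributes.
#' `contract` replaces each equivalence class by its lexicographically
#' smallest member and rewires all non-mapping edges onto the canonical node;
#' the multiset of non-mapping edges is conserved.
#'
#' @param g a `pgx_graph`.
#' @param m data.frame of mappings (`left`, `right`, `method`).
#' @param mode `"edge"` or `"contract"`.
#' @return The transformed `pgx_graph`.
#' @export
pgx_merge_equivalents <- function(g, m, mode = c("edge", "contract")) {
  mode <- match.arg(mode)
  if (is.null(m) || nrow(m) == 0L) return(g)
  missing <- setdiff(unique(c(m$left, m$right)), g$nodes$label)
  if (length(missing))
    stop("mappings reference absent nodes: ", paste(missing, collapse = ", "))
  if (mode == "edge") {
    have <- paste(g$edges$subject, g$edges$predicate, g$edges$object)
    new_e <- data.frame(
      subject = c(m$left, m$right), predicate = PX_MAPPED_TO,
      object = c(m$right, m$left))
    new_e <- new_e[!(paste(new_e$subject, new_e$predicate, new_e$object)
                     %in% have), ]
    g$edges <- rbind(g$edges, new_e)
    both <- rbind(g$mappings, m[, c("left", "right", "method")])
    g$mappings <- unique(both)
    rownames(g$edges) <- rownames(g$mappings) <- NULL
    return(validate_pgx_graph(g))
  }
  canon <- equivalence_canonical(g$nodes$label, m)
  e <- g$edges[g$edges$predicate != PX_MAPPED_TO, ]
  e$subject <- unname(canon[e$subject])
  e$object <- unname(canon[e$object])
  keep <- !duplicated(unname(canon[g$nodes$label]))
  nodes <- g$nodes[keep, ]
  nodes$label <- unname(canon[nodes$label])
  g2 <- pgx_graph(nodes[order(nodes$label), ], e, NULL)
  g2
}

# --- pair nodes and direction normalisation ---------------------------------

pair_node_label <- function(gene, drug) paste0("pair:", gene, "__", drug)

#' Add gene--drug pair nodes (and class nodes) to the graph
#'
#' Link prediction is recast as node classification: each candidate pair
#' becomes a dedicated node with exactly two structural edges, to its gene
#' and to its drug. Pairs labelled `associated` / `not_associated`
#' additionally get a `px:is_a` edge to the matching class node. Re-adding an
#' existing pair is a no-op.
#'
#' @param g a `pgx_graph`.
#' @param pairs data.frame with columns `gene`, `drug` and optionally `label`
#'   (`associated`, `not_associated`, `unknown`).
#' @return The augmented `pgx_graph`.
#' @export
pgx_add_pair_nodes <- function(g, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(g)
  if (!"label" %in% names(pairs)) pairs$label <- "unknown"
  absent <- !(pairs$gene %in% g$nodes$label) | !(pairs$drug %in% g$nodes$label)
  if (any(absent))
    stop("pair(s) reference absent gene or drug: ",
         paste(paste0(pairs$gene[absent], "-", pairs$drug[absent])[
           seq_len(min(5L, sum(absent)))], collapse = ", "))
  pl <- pair_node_label(pairs$gene, pairs$drug)
  fresh <- !(pl %in% g$nodes$label) & !duplicated(pl)
  pairs <- pairs[fresh, ]; pl <- pl[fresh]
  if (!nrow(pairs)) return(g)
  new_nodes <- data.frame(label = pl, type = "GeneDrugPairNode")
  need_class <- unique(ifelse(pairs$label == "associated", CLASS_POS,
                              ifelse(pairs$label == "not_associated",
                                     CLASS_NEG, NA_character_)))
  need_class <- setdiff(need_class[!is.na(need_class)], g$nodes$label)
  if (length(need_class))
    new_nodes <- rbind(new_nodes,
                       data.frame(label = need_class, type = "ClassNode"))
  e <- rbind(
    data.frame(subject = pl, predicate = PX_HAS_GENE, object = pairs$gene),
    data.frame(subject = pl, predicate = PX_HAS_DRUG, object = pairs$drug))
  lab <- pairs$label
  cls <- ifelse(lab == "associated", CLASS_POS,
                ifelse(lab == "not_associated", CLASS_NEG, NA_character_))
  has_cls <- !is.na(cls)
  if (any(has_cls))
    e <- rbind(e, data.frame(subject = pl[has_cls], predicate = PX_IS_A,
                             object = cls[has_cls]))
  g$nodes <- rbind(g$nodes, new_nodes)
  g$edges <- rbind(g$edges, e)
  rownames(g$nodes) <- rownames(g$edges) <- NULL
  validate_pgx_graph(g)
}

#' Remove all pair and class nodes
#'
#' Inverse of [pgx_add_pair_nodes()]: drops every `GeneDrugPairNode` and
#' `ClassNode` together with their incident edges, restoring the entity graph.
#'
#' @param g a `pgx_graph`.
#' @return The reduced `pgx_graph`.
#' @export
pgx_remove_pair_nodes <- function(g) {
  drop <- g$nodes$label[g$nodes$type %in% c("GeneDrugPairNode", "ClassNode")]
  g$nodes <- g$nodes[!(g$nodes$label %in% drop), ]
  g$edges <- g$edges[!(g$edges$subject %in% drop) &
                     !(g$edges$object %in% drop), ]
  rownames(g$nodes) <- rownames(g$edges) <- NULL
  g
}

#' Normalise edge directions for one-way kernel exploration
#'
#' Kernel neighbourhood extraction follows predicates in a single direction.
#' Every edge whose predicate appears in `inversion_rules` is replaced by its
#' reverse, with the predicate renamed `<p>_inv`; all other edges are left
#' untouched. Total edge count is preserved, and applying the rules a second
#' time (with the `_inv` names) restores an isomorphic graph.
#'
#' @param g a `pgx_graph`.
#' @param inversion_rules character vector of predicate labels to invert.
#' @return The `pgx_graph` with inverted edges.
#' @export
pgx_normalize_directions <- function(g, inversion_rules) {
  if (!length(inversion_rules) || nrow(g$edges) == 0L) return(g)
  hit <- g$edges$predicate %in% inversion_rules
  if (any(hit)) {
    s <- g$edges$subject[hit]
    g$edges$subject[hit] <- g$edges$object[hit]
    g$edges$object[hit] <- s
    p <- g$edges$predicate[hit]
    g$edges$predicate[hit] <- ifelse(endsWith(p, "_inv"),
                                     sub("_inv$", "", p), paste0(p, "_inv"))
  }
  g
}

#' Load-report accessor
#' @param g a `pgx_graph` returned by [pgx_load_graph()].
#' @return The load report list, or `NULL`.
#' @export
pgx_load_report <- function(g) attr(g, "load_report")
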