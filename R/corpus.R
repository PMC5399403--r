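# Training / test pair-set construction from variant-level evidence
# annotations, with exclusion-aware negative sampling.

#' Collapse variant-level annotations to gene--drug pairs
#'
#' Clinical evidence annotations relate gene *variants* to drugs, each with an
#' evidence level 1 (best validated) to 4 (weakest). Several variants of one
#' gene may reach the same drug at different levels; the pair keeps the best
#' (numerically smallest) level. E.g. VKORC1 variants reach warfarin at
#' levels 1--4: the collapsed pair is VKORC1--warfarin at level 1.
#'
#' @param annotations data.frame with columns `gene`, `variant_id`, `drug`,
#'   `evidence_level` (integers 1--4).
#' @return data.frame of distinct pairs (`gene`, `drug`, `evidence_level`),
#'   sorted by gene then drug.
#' @export
pgx_collapse_variants <- function(annotations) {
  empty <- data.frame(gene = character(), drug = character(),
                      evidence_level = integer())
  if (is.null(annotations) || nrow(annotations) == 0L) return(empty)
  lv <- annotations$evidence_level
  bad <- is.na(lv) | !(lv %in% 1:4)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("evidence level outside 1-4 for annotation ", annotations$gene[i],
         "/", annotations$variant_id[i], "/", annotations$drug[i],
         " (level = ", lv[i], ")")
  }
  agg <- aggregate(evidence_level ~ gene + drug, data = annotations, FUN = min)
  agg <- agg[order(agg$gene, agg$drug), c("gene", "drug", "evidence_level")]
  agg$evidence_level <- as.integer(agg$evidence_level)
  rownames(agg) <- NULL
  agg
}

#' Select well-validated pairs as positive training examples
#'
#' Positives are the collapsed pairs with evidence level 1 or 2.
#'
#' @param pairs collapsed pair data.frame (`gene`, `drug`, `evidence_level`).
#' @return data.frame with an added `label = "associated"` column, sorted by
#'   gene then drug.
#' @export
pgx_select_positives <- function(pairs) {
  out <- pairs[!is.na(pairs$evidence_level) & pairs$evidence_level %in% 1:2, ,
               drop = FALSE]
  out <- out[order(out$gene, out$drug), , drop = FALSE]
  out$label <- rep("associated", nrow(out))
  rownames(out) <- NULL
  out
}

#' Select insufficiently validated pairs as the test set
#'
#' Test candidates are the collapsed pairs with evidence level 3 or 4; the
#' classifiers are asked to prioritise these.
#'
#' @param pairs collapsed pair data.frame.
#' @return data.frame with `label = "unknown"`, sorted by gene then drug.
#' @export
pgx_select_test <- function(pairs) {
  out <- pairs[!is.na(pairs$evidence_level) & pairs$evidence_level %in% 3:4, ,
               drop = FALSE]
  out <- out[order(out$gene, out$drug), , drop = FALSE]
  out$label <- rep("unknown", nrow(out))
  rownames(out) <- NULL
  out
}

#' Sample negative gene--drug pairs against an exclusion list
#'
#' Draws `n` distinct pairs uniformly without replacement from
#' `gene_pool x drug_pool` minus the exclusion set (pairs with any known or
#' suspected interaction). Pools and the admissible set are sorted before the
#' seeded shuffle, so results are identical across platforms.
#'
#' @param gene_pool,drug_pool character vectors of candidate entity labels.
#' @param exclusion data.frame (`gene`, `drug`) of inadmissible pairs.
#' @param n number of negatives requested.
#' @param seed integer seed.
#' @return data.frame (`gene`, `drug`, `evidence_level = NA`,
#'   `label = "not_associated"`).
#' @export
pgx_sample_negatives <- function(gene_pool, drug_pool, exclusion, n, seed = 1L) {
  stopifnot(n >= 0L)
  if (n == 0L)
    return(data.frame(gene = character(), drug = character(),
                      evidence_level = integer(), label = character()))
  if (!length(gene_pool) || !length(drug_pool))
    stop("empty gene or drug pool")
  gene_pool <- sort(unique(gene_pool))
  drug_pool <- sort(unique(drug_pool))
  all_pairs <- expand.grid(gene = gene_pool, drug = drug_pool,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(all_pairs$gene, all_pairs$drug, sep = "\r")
  excl_key <- if (!is.null(exclusion) && nrow(exclusion))
    paste(exclusion$gene, exclusion$drug, sep = "\r") else character()
  adm <- all_pairs[!(key %in% excl_key), , drop = FALSE]
  if (nrow(adm) < n)
    stop("only ", nrow(adm), " admissible pairs but ", n, " requested")
  adm <- adm[order(adm$gene, adm$drug), , drop = FALSE]
  idx <- with_preserved_rng({
    set.seed(seed)
    sample.int(nrow(adm), n)
  })
  out <- adm[idx, , drop = FALSE]
  out$evidence_level <- NA_integer_
  out$label <- "not_associated"
  rownames(out) <- NULL
  out
}

# Run expr with the caller's RNG state restored afterwards.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
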