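# Classifiers, bag aggregation, repeated nested cross-validation, metrics,
# and candidate ranking/combination.

#' Aggregate instance probabilities into a signed bag score
#'
#' A gene--drug pair is a bag of instances. Each instance `j` contributes its
#' model confidence `p_ij`, signed by its predicted class: `+p_ij` if
#' classified associated, `-p_ij` otherwise; the bag score is the mean over
#' the bag, so it always lies in `[-1, 1]`. Unlike the max or plain-mean
#' operators, a bag mixing confidently positive and confidently negative
#' instances lands near 0 rather than being forced positive.
#'
#' @param p numeric vector of instance confidences in `[0, 1]`.
#' @param class integer/numeric vector of instance decisions (1 = associated,
#'   0 = not).
#' @return The bag score in `[-1, 1]`.
#' @export
pgx_aggregate_bag <- function(p, class) {
  if (!length(p)) stop("empty bag: a pair with no instances must not be scored")
  stopifnot(length(p) == length(class), all(class %in% c(0, 1)))
  sum(ifelse(class == 1, 1, -1) * p) / length(p)
}

#' Train a random forest on the instance-level feature matrix
#'
#' Wraps an established forest implementation (ranger) behind the
#' multi-instance interface: the model predicts per-instance class
#' probabilities, which [pgx_score_pairs()] aggregates into bag scores. The
#' training vocabulary is frozen inside the model so test rows are encoded
#' onto identical columns.
#'
#' @param m a `pgx_feature_matrix` whose labelled rows (classes `"0"`/`"1"`)
#'   are used; both classes must be present.
#' @param num_trees number of trees.
#' @param seed integer seed (training is deterministic under it).
#' @return A `pgx_forest` model.
#' @export
pgx_train_forest <- function(m, num_trees = 300L, seed = 1L) {
  lab <- m$y %in% c("0", "1")
  y <- factor(m$y[lab], levels = c("0", "1"))
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contain a single class")
  X <- as.matrix(m$X[lab, , drop = FALSE])
  fit <- ranger::ranger(x = X, y = y, probability = TRUE,
                        num.trees = num_trees, seed = seed,
                        num.threads = 1L)
  structure(list(fit = fit, vocab = m$vocab, slots = m$slots,
                 num_trees = num_trees, seed = seed),
            class = "pgx_forest")
}

# Per-instance probabilities and decisions for categorical rows, encoded
# with the model's frozen vocabulary.
predict_instances <- function(model, rows) {
  m <- pgx_build_matrix(rows, vocab = model$vocab)
  pr <- stats::predict(model$fit, data = as.matrix(m$X))$predictions
  p_pos <- pr[, "1"]
  cls <- as.integer(p_pos >= 0.5)
  data.frame(pair_id = rows$pair_id, p_pos = p_pos,
             p_ij = ifelse(cls == 1L, p_pos, 1 - p_pos), class_ij = cls)
}

#' Train a C-SVC on a precomputed kernel
#'
#' Soft-margin support vector classification on the pair-node kernel. When
#' `C` is `NULL` it is selected by stratified inner cross-validation over
#' `C_grid` (maximising weighted F). Class probabilities come from a
#' sigmoid (Platt-style) calibration fitted on out-of-fold decision values
#' (training-fit margins are overconfident), so `p_GK` is rank-faithful to
#' the margin and its 0.5 threshold is meaningful.
#'
#' @param K symmetric PSD kernel matrix over the training pairs.
#' @param labels vector of `"associated"` / `"not_associated"` (or 1/0).
#' @param C cost parameter; `NULL` triggers inner-CV selection.
#' @param C_grid candidate costs for the inner search.
#' @param inner_folds inner cross-validation folds.
#' @param seed integer seed for the inner folds.
#' @return A `pgx_svm` model (keeps support-vector indices relative to the
#'   training kernel and the calibration map).
#' @export
pgx_train_svm <- function(K, labels, C = NULL, C_grid = c(0.1, 1, 10, 100),
                          inner_folds = 10L, seed = 1L) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  stopifnot(nrow(K) == length(y), ncol(K) == length(y))
  if (max(abs(K - t(K))) > 1e-8) stop("kernel matrix is not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(1, abs(ev[1L])))
    stop("kernel matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  folds <- stratified_folds(y, min(inner_folds,
                                   min(table(y)) %/% 2L + 1L), seed)
  if (is.null(C)) {
    C <- if (length(C_grid) == 1L) C_grid
         else select_svm_C(K, y, folds, C_grid)
  }
  # sigmoid calibration on out-of-fold decision values: training-fit margins
  # are overconfident and would misplace the 0.5 threshold
  dv_oof <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(y[tr])) < 2L || !length(te)) next
    fit_f <- fit_ksvm(K[tr, tr, drop = FALSE], y[tr], C)
    flip_f <- dv_orientation(fit_f, K[tr, tr, drop = FALSE], y[tr])
    dv_oof[te] <- flip_f * decision_values(fit_f, K[te, tr, drop = FALSE])
  }
  fit <- fit_ksvm(K, y, C)
  flip <- dv_orientation(fit, K, y)
  dv <- ifelse(is.na(dv_oof), flip * decision_values(fit, K), dv_oof)
  cal <- suppressWarnings(glm(y ~ dv, family = binomial(),
                              data = data.frame(y = y, dv = dv)))
  structure(list(fit = fit, C = C, flip = flip, calibration = cal,
                 n_train = length(y)),
            class = "pgx_svm")
}

# Decision-value orientation: +1 if larger values indicate the positive
# class on the training data, else -1 (the raw sign is arbitrary).
dv_orientation <- function(fit, K_train, y) {
  dv <- decision_values(fit, K_train)
  if (mean(dv[y == 1]) >= mean(dv[y == 0])) 1 else -1
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    out <- ifelse(labels %in% c("associated", "1"), 1L,
                  ifelse(labels %in% c("not_associated", "0"), 0L, NA))
    if (anyNA(out)) stop("unrecognised labels")
    out
  } else as.integer(labels)
}

fit_ksvm <- function(K, y, C) {
  kernlab::ksvm(kernlab::as.kernelMatrix(K),
                factor(y, levels = c("0", "1")),
                type = "C-svc", C = C, scaled = FALSE)
}

decision_values <- function(fit, K_new_train) {
  sv <- kernlab::SVindex(fit)
  as.numeric(kernlab::predict(
    fit, kernlab::as.kernelMatrix(K_new_train[, sv, drop = FALSE]),
    type = "decision"))
}

select_svm_C <- function(K, y, folds, C_grid) {
  score <- vapply(C_grid, function(C) inner_cv_score(K, y, folds, C), 0)
  C_grid[which.max(score)]
}

inner_cv_score <- function(K, y, folds, C) {
  f1 <- vapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(y[tr])) < 2L || !length(te)) return(NA_real_)
    fit <- fit_ksvm(K[tr, tr, drop = FALSE], y[tr], C)
    flip <- dv_orientation(fit, K[tr, tr, drop = FALSE], y[tr])
    pred <- as.integer(flip * decision_values(fit, K[te, tr,
                                                    drop = FALSE]) > 0)
    pgx_evaluate_metrics(y[te], prob = NULL, decision = pred)$weighted_F
  }, 0)
  mean(f1, na.rm = TRUE)
}

# Joint inner-fold selection of kernel setting and cost over a named list of
# candidate kernels; returns the winning kernel name and C.
select_svm_kernel <- function(K_list, y, folds, C_grid) {
  grid <- expand.grid(k = seq_along(K_list), C = C_grid)
  score <- vapply(seq_len(nrow(grid)), function(i)
    inner_cv_score(K_list[[grid$k[i]]], y, folds, grid$C[i]), 0)
  best <- which.max(score)
  list(kernel = grid$k[best], C = grid$C[best])
}

#' Score pairs with a trained model
#'
#' Forest branch: predicts per-instance probabilities on the pair's bag,
#' takes each instance's decision and confidence, and aggregates them with
#' the signed weighted mean ([pgx_aggregate_bag()]); the bag score `p_RF`
#' lies in `[-1, 1]` and `prob` is its `(p + 1) / 2` display transform.
#' Kernel branch: applies the calibrated SVM to the test-vs-training kernel
#' rows; `p_GK = prob` lies in `[0, 1]`.
#'
#' @param model a `pgx_forest` or `pgx_svm`.
#' @param newdata forest: categorical instance rows ([pgx_build_bags()]);
#'   SVM: numeric matrix `K[test, train]` with pair ids as row names.
#' @param ... unused.
#' @return data.frame (`pair_id`, `score`, `prob`) in a deterministic order.
#' @export
pgx_score_pairs <- function(model, newdata, ...) UseMethod("pgx_score_pairs")

#' @export
pgx_score_pairs.pgx_forest <- function(model, newdata, ...) {
  if (!nrow(newdata))
    return(data.frame(pair_id = character(), score = numeric(),
                      prob = numeric()))
  inst <- predict_instances(model, newdata)
  sp <- split(inst, inst$pair_id)
  score <- vapply(sp, function(b) pgx_aggregate_bag(b$p_ij, b$class_ij), 0)
  out <- data.frame(pair_id = names(sp), score = unname(score),
                    prob = (unname(score) + 1) / 2)
  attr(out, "instances") <- inst  # per-instance audit trail
  out[order(out$pair_id), , drop = FALSE]
}

#' @export
pgx_score_pairs.pgx_svm <- function(model, newdata, ...) {
  if (!nrow(newdata))
    return(data.frame(pair_id = character(), score = numeric(),
                      prob = numeric()))
  dv <- model$flip * decision_values(model$fit, newdata)
  p <- as.numeric(predict(model$calibration,
                          newdata = data.frame(dv = dv), type = "response"))
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(newdata)))
  out <- data.frame(pair_id = ids, score = p, prob = p)
  out[order(out$pair_id), , drop = FALSE]
}

# --- metrics ----------------------------------------------------------------

#' Classification metrics from truth, probabilities and decisions
#'
#' Per-class precision/recall/F from the confusion matrix, the
#' prevalence-weighted and macro-averaged F, AUC-ROC by the rank statistic,
#' and the RMSE between the probability of the positive class and the 0/1
#' truth. With single-class truth the AUC is reported as `NA`.
#'
#' @param truth 0/1 vector.
#' @param prob probability of the positive class (`NULL` skips AUC/RMSE).
#' @param decision 0/1 decisions; defaults to `prob >= 0.5`.
#' @return list with `per_class` (data.frame), `weighted_F`, `macro_F`,
#'   `auc`, `rmse`, `accuracy`.
#' @export
pgx_evaluate_metrics <- function(truth, prob = NULL, decision = NULL) {
  truth <- as.integer(truth)
  if (is.null(decision)) decision <- as.integer(prob >= 0.5)
  stopifnot(length(truth) == length(decision))
  prf <- function(cls) {
    tp <- sum(truth == cls & decision == cls)
    fp <- sum(truth != cls & decision == cls)
    fn <- sum(truth == cls & decision != cls)
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    c(precision = pr, recall = rc, F = f)
  }
  per <- rbind(`1` = prf(1L), `0` = prf(0L))
  w <- c(mean(truth == 1L), mean(truth == 0L))
  auc <- NA_real_
  rmse <- NA_real_
  if (!is.null(prob)) {
    n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
    if (n1 > 0L && n0 > 0L) {
      r <- rank(prob)
      auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    rmse <- sqrt(mean((prob - truth)^2))
  }
  list(per_class = data.frame(class = c("1", "0"),
                              precision = per[, "precision"],
                              recall = per[, "recall"], F = per[, "F"]),
       weighted_F = sum(w * per[, "F"]),
       macro_F = mean(per[, "F"]),
       auc = auc, rmse = rmse,
       accuracy = mean(truth == decision))
}

# Stratified fold assignment over labels; deterministic under seed.
stratified_folds <- function(y, folds, seed) {
  out <- integer(length(y))
  with_preserved_rng({
    set.seed(seed)
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      out[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  out
}

# --- repeated nested cross-validation ---------------------------------------

#' Repeated stratified nested cross-validation of either branch
#'
#' Outer protocol: `folds`-fold cross-validation stratified at the *pair*
#' level (all instances of a bag stay in one fold; splitting a bag is a hard
#' error), repeated `repeats` times; the fold seed of repeat `r` is
#' `bitwXor(seed, r)`, so each repeat is individually reproducible. Within
#' each training fold the SVM cost `C` is selected by inner cross-validation
#' without touching the outer test fold. Predictions are pooled per repeat
#' and metrics averaged over repeats.
#'
#' @param dataset forest branch (`learner = "rf"`): list with `rows`
#'   (instance rows from [pgx_build_bags()]) and `pairs` (data.frame `gene`,
#'   `drug`, `label`). Kernel branch (`"gk"`): list with `K` (a kernel
#'   matrix aligned with `pairs` rows, or a list of candidate kernel
#'   matrices among which the inner cross-validation selects, jointly with
#'   `C`) and `pairs`.
#' @param learner `"rf"` or `"gk"`.
#' @param folds,repeats outer protocol size.
#' @param inner_folds inner folds for hyperparameter selection.
#' @param seed base seed.
#' @param C_grid SVM cost grid.
#' @param num_trees forest size.
#' @return A `pgx_cv_report`: per-repeat metrics, their mean and sd, and the
#'   protocol settings.
#' @export
pgx_crossvalidate <- function(dataset, learner = c("rf", "gk"), folds = 10L,
                              repeats = 10L, inner_folds = 10L, seed = 1L,
                              C_grid = c(0.1, 1, 10, 100), num_trees = 300L) {
  learner <- match.arg(learner)
  pairs <- dataset$pairs
  key <- paste(pairs$gene, pairs$drug, sep = "|")
  y <- as_binary_labels(pairs$label)
  uk <- unique(key)
  uy <- y[match(uk, key)]
  if (any(tapply(y, key, function(v) length(unique(v))) > 1L))
    stop("conflicting labels within a pair identity")
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rs <- bitwXor(as.integer(seed), r)
    fold_of_key <- stratified_folds(uy, folds, rs)
    fold <- fold_of_key[match(key, uk)]
    if (learner == "rf") {
      rows <- dataset$rows
      inst_fold <- fold_of_key[match(rows$pair_id, uk)]
      if (anyNA(inst_fold))
        stop("instance rows reference pairs outside the dataset")
      if (any(tapply(inst_fold, rows$pair_id,
                     function(v) length(unique(v))) > 1L))
        stop("bag split across folds")  # leakage guard
    }
    prob <- numeric(length(uk)); dec <- integer(length(uk))
    for (f in seq_len(folds)) {
      te_keys <- uk[fold_of_key == f]
      tr_keys <- uk[fold_of_key != f]
      if (learner == "rf") {
        rows <- dataset$rows
        tr_rows <- rows[rows$pair_id %in% tr_keys, , drop = FALSE]
        te_rows <- rows[rows$pair_id %in% te_keys, , drop = FALSE]
        m_tr <- pgx_build_matrix(tr_rows)
        model <- pgx_train_forest(m_tr, num_trees = num_trees,
                                  seed = rs * 100L + f)
        sc <- pgx_score_pairs(model, te_rows)
        ix <- match(sc$pair_id, uk)
        prob[ix] <- sc$prob
        dec[ix] <- as.integer(sc$score > 0)
      } else {
        tr <- which(key %in% tr_keys); te <- which(key %in% te_keys)
        K_list <- dataset$K
        if (!is.list(K_list)) K_list <- list(K_list)
        if (length(K_list) > 1L) {
          # paper-style protocol: kernel settings are optimised inside the
          # training fold alongside C
          ytr <- y[tr]
          ifolds <- stratified_folds(
            ytr, min(inner_folds, min(table(ytr)) %/% 2L + 1L),
            rs * 100L + f)
          sub <- lapply(K_list, function(Ki) Ki[tr, tr, drop = FALSE])
          sel <- select_svm_kernel(sub, ytr, ifolds, C_grid)
          Kbest <- K_list[[sel$kernel]]
          model <- pgx_train_svm(Kbest[tr, tr, drop = FALSE], ytr,
                                 C = sel$C, inner_folds = inner_folds,
                                 seed = rs * 100L + f)
        } else {
          Kbest <- K_list[[1L]]
          model <- pgx_train_svm(Kbest[tr, tr, drop = FALSE], y[tr],
                                 C = NULL, C_grid = C_grid,
                                 inner_folds = inner_folds,
                                 seed = rs * 100L + f)
        }
        Kte <- Kbest[te, tr, drop = FALSE]
        rownames(Kte) <- key[te]
        sc <- pgx_score_pairs(model, Kte)
        ix <- match(sc$pair_id, uk)
        prob[ix] <- sc$prob
        dec[ix] <- as.integer(sc$prob >= 0.5)
      }
    }
    met <- pgx_evaluate_metrics(uy, prob = prob, decision = dec)
    per_repeat[[r]] <- data.frame(
      repeat_id = r, seed = rs,
      F_pos = met$per_class$F[1L], F_neg = met$per_class$F[2L],
      weighted_F = met$weighted_F, macro_F = met$macro_F,
      auc = met$auc, rmse = met$rmse, accuracy = met$accuracy)
  }
  tab <- do.call(rbind, per_repeat)
  mcols <- c("F_pos", "F_neg", "weighted_F", "macro_F", "auc", "rmse",
             "accuracy")
  structure(list(per_repeat = tab,
                 mean = colMeans(tab[mcols]),
                 sd = vapply(tab[mcols], sd, 0),
                 folds = folds, repeats = repeats,
                 inner_folds = inner_folds, seed = seed, learner = learner),
            class = "pgx_cv_report")
}

#' @importFrom stats sd
#' @method print pgx_cv_report
#' @export
print.pgx_cv_report <- function(x, ...) {
  cat("<pgx_cv_report> ", x$learner, " branch, ", x$folds, "-fold CV x ",
      x$repeats, " repeats\n", sep = "")
  m <- x$mean
  cat(sprintf("  weighted F = %.3f (sd %.3f)   macro F = %.3f   AUC = %.3f   RMSE = %.3f\n",
              m["weighted_F"], x$sd["weighted_F"], m["macro_F"], m["auc"],
              m["rmse"]))
  invisible(x)
}

# --- ranking ----------------------------------------------------------------

#' Intersect and rank the two branches' top candidates
#'
#' Takes each branch's top-`k` pairs by its own score (descending), keeps
#' the pairs present in both lists, sorts the intersection by descending
#' forest score `p_RF` (ties: descending `p_GK`, then lexicographic pair
#' identity), and assigns consecutive ranks from 1.
#'
#' @param rf data.frame (`gene`, `drug`, `score`) from the forest branch.
#' @param gk data.frame (`gene`, `drug`, `score`) from the kernel branch.
#' @param k top-list size (default 20); a `k` larger than a list uses the
#'   whole list with a warning.
#' @return data.frame (`rank`, `gene`, `drug`, `p_RF`, `p_GK`).
#' @export
pgx_combine_rankings <- function(rf, gk, k = 20L) {
  if (k > nrow(rf) || k > nrow(gk))
    warning("k exceeds a candidate list; using the whole list")
  top <- function(d) {
    d <- d[order(-d$score, d$gene, d$drug), , drop = FALSE]
    head(d, k)
  }
  t_rf <- top(rf); t_gk <- top(gk)
  key_rf <- paste(t_rf$gene, t_rf$drug, sep = "|")
  key_gk <- paste(t_gk$gene, t_gk$drug, sep = "|")
  both <- intersect(key_rf, key_gk)
  if (!length(both))
    return(data.frame(rank = integer(), gene = character(),
                      drug = character(), p_RF = numeric(),
                      p_GK = numeric()))
  i_rf <- match(both, key_rf); i_gk <- match(both, key_gk)
  out <- data.frame(gene = t_rf$gene[i_rf], drug = t_rf$drug[i_rf],
                    p_RF = t_rf$score[i_rf], p_GK = t_gk$score[i_gk])
  out <- out[order(-out$p_RF, -out$p_GK, out$gene, out$drug), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
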