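# Evaluation: confusion metrics, ROC/PR areas, repeated k-fold
# cross-validation with SMOTE confined to training folds, and the
# leave-one-association-out new-drug ranking experiment.

#' Confusion counts at a score threshold
#'
#' @param labels binary vector.
#' @param scores vector of scores in `[0, 1]`, same length.
#' @param threshold scores `>= threshold` are called positive.
#' @return list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) {
    stop_fusedda("empty label vector", "fusedda_validation_error")
  }
  if (length(labels) != length(scores)) {
    stop_fusedda("labels and scores differ in length",
                 "fusedda_dimension_error")
  }
  pred <- scores >= threshold
  list(TP = sum(labels == 1 & pred),
       FN = sum(labels == 1 & !pred),
       FP = sum(labels == 0 & pred),
       TN = sum(labels == 0 & !pred))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `Acc = (TP+TN)/total`, `Prec = TP/(TP+FP)`, `Rec = TP/(TP+FN)`,
#' `F1 = 2 * Prec * Rec / (Prec + Rec)`; a metric whose denominator is 0
#' is defined as 0.
#'
#' @param c a confusion-count list as returned by [confusion_counts()].
#' @return named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  stopifnot(total > 0)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(c$TP, c$TP + c$FP)
  recall <- safe_div(c$TP, c$TP + c$FN)
  list(accuracy = (c$TP + c$TN) / total,
       precision = precision,
       recall = recall,
       f1 = safe_div(2 * precision * recall, precision + recall))
}

#' Area under the ROC or precision-recall curve
#'
#' ROC: trapezoidal area under TPR vs FPR over all score thresholds, tied
#' scores grouped into a single threshold step. PR: step-wise
#' (average-precision) rule — precision at each threshold weighted by the
#' recall increment it contributes.
#'
#' @param labels binary vector with both classes present.
#' @param scores numeric score vector.
#' @param mode `"roc"` or `"pr"`.
#' @return list with `auc` and a `curve` data frame (`fpr`/`tpr` or
#'   `recall`/`precision`).
#' @export
curve_auc <- function(labels, scores, mode = c("roc", "pr")) {
  mode <- match.arg(mode)
  if (length(unique(labels)) < 2) {
    stop_fusedda("both classes must be present to draw a curve",
                 "fusedda_validation_error")
  }
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores: cumulative counts at the end of each tie group
  grp_end <- which(c(diff(s) != 0, TRUE))
  cum_tp <- cumsum(l == 1)[grp_end]
  cum_fp <- cumsum(l == 0)[grp_end]
  if (mode == "roc") {
    tpr <- c(0, cum_tp / P)
    fpr <- c(0, cum_fp / N)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
  } else {
    rec <- cum_tp / P
    prec <- cum_tp / (cum_tp + cum_fp)
    d_rec <- diff(c(0, rec))
    auc <- sum(d_rec * prec)
    list(auc = auc, curve = data.frame(recall = c(0, rec),
                                       precision = c(1, prec)))
  }
}

#' Seeded k-fold index split
#'
#' @param num_rows number of rows to split.
#' @param k fold count, `2 <= k <= num_rows`.
#' @param seed integer seed.
#' @return list of `k` disjoint integer index vectors whose union covers
#'   `1:num_rows`; fold sizes differ by at most 1.
#' @export
kfold_split <- function(num_rows, k, seed = 1L) {
  if (k < 2 || k > num_rows) {
    stop_fusedda(sprintf("k must satisfy 2 <= k <= %d", num_rows),
                 "fusedda_parameter_error")
  }
  perm <- withr::with_seed(seed, sample.int(num_rows))
  folds <- split(perm, rep(seq_len(k), length.out = num_rows))
  names(folds) <- NULL
  folds  # sizes num_rows %/% k, the first num_rows %% k folds one larger

}

# internal: evaluate scored test fold into one metrics row
fold_metrics <- function(labels, scores, threshold) {
  cc <- confusion_counts(labels, scores, threshold)
  cm <- classification_metrics(cc)
  both <- length(unique(labels)) == 2
  data.frame(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
             accuracy = cm$accuracy, precision = cm$precision,
             recall = cm$recall, f1 = cm$f1,
             auroc = if (both) curve_auc(labels, scores, "roc")$auc else NA_real_,
             aupr = if (both) curve_auc(labels, scores, "pr")$auc else NA_real_)
}

#' Repeated k-fold cross-validation of the full training stage
#'
#' For every round and fold: SMOTE is applied to the training portion only
#' (never to the test fold), a fresh network is trained on it, and the
#' untouched test fold is scored. Rounds reshuffle the folds with a fresh
#' sub-seed. The full-scale protocol is `k = 5`, 150 rounds; test
#' profiles use small round counts.
#'
#' @param table an observed (un-balanced) `pair_table`.
#' @param net_cfg a [network_config()].
#' @param bal_cfg a [balance_config()]; `NULL` disables balancing.
#' @param k fold count (default 5).
#' @param rounds repetition count (default 1).
#' @param seed master seed; folds, SMOTE and training derive sub-seeds
#'   from it.
#' @param smote_in_folds apply SMOTE inside training folds (default
#'   `TRUE`); `FALSE` balances the whole table once before splitting (the
#'   leaky variant, for reproduction attempts only).
#' @return an object of class `evaluation_report`: `$per_fold` data frame
#'   (round, fold, counts, metrics), `$aggregate` named means over folds,
#'   `$dispersion` standard deviations, and `$curves` (ROC and PR points
#'   of the pooled last round).
#' @export
cross_validate <- function(table, net_cfg = network_config(),
                           bal_cfg = balance_config(), k = 5L, rounds = 1L,
                           seed = 1L, smote_in_folds = TRUE) {
  stopifnot(inherits(table, "pair_table"))
  if (!smote_in_folds && !is.null(bal_cfg)) {
    bal_cfg$seed <- seed
    table <- smote(table, bal_cfg)
  }
  nrows <- length(table$label)
  rows <- list()
  pooled_labels <- numeric(0)
  pooled_scores <- numeric(0)
  for (r in seq_len(rounds)) {
    round_seed <- seed + 1000L * (r - 1L)
    folds <- kfold_split(nrows, k, seed = round_seed)
    for (f in seq_len(k)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(nrows), test_idx)
      tr <- pair_table_subset(table, train_idx)
      te <- pair_table_subset(table, test_idx)
      stopifnot(all(te$provenance == "observed") || !smote_in_folds)
      if (smote_in_folds && !is.null(bal_cfg)) {
        bc <- bal_cfg
        bc$seed <- round_seed + f
        tr <- smote(tr, bc)
      }
      nc <- net_cfg
      nc$seed <- round_seed + 100L * f
      model <- build_model(ncol(tr$features), nc)
      model <- train(model, tr, nc)
      sc <- predict_scores(model, te$features)
      fm <- fold_metrics(te$label, sc, net_cfg$threshold)
      rows[[length(rows) + 1]] <- cbind(data.frame(round = r, fold = f), fm)
      if (r == rounds) {
        pooled_labels <- c(pooled_labels, te$label)
        pooled_scores <- c(pooled_scores, sc)
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auroc", "aupr")
  aggregate <- colMeans(per_fold[, metric_cols], na.rm = TRUE)
  dispersion <- apply(per_fold[, metric_cols], 2, stats::sd, na.rm = TRUE)
  curves <- if (length(unique(pooled_labels)) == 2) {
    list(roc = curve_auc(pooled_labels, pooled_scores, "roc")$curve,
         pr = curve_auc(pooled_labels, pooled_scores, "pr")$curve)
  } else NULL
  structure(list(per_fold = per_fold, aggregate = as.list(aggregate),
                 dispersion = as.list(dispersion), curves = curves,
                 k = k, rounds = rounds, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d-fold x %d round(s)>\n", x$k, x$rounds))
  cat(sprintf("  mean accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f\n",
              x$aggregate$accuracy, x$aggregate$precision,
              x$aggregate$recall, x$aggregate$f1))
  cat(sprintf("  mean AUROC %.4f  AUPR %.4f\n",
              x$aggregate$auroc, x$aggregate$aupr))
  invisible(x)
}

#' New-drug indication ranking (leave-one-association-out)
#'
#' For each drug with exactly one known associated disease, that
#' association is removed, a model trained without it ranks all diseases
#' for the drug, and the drug scores a success when the withheld disease
#' ranks first (precision 1.0 in the top-1 sense). By default one shared
#' model is trained with all the subset drugs' associations removed;
#' `mode = "per_drug"` retrains for every drug. Ties in the ranking break
#' towards the smaller disease index.
#'
#' @param UDRS,UDIS fused similarity matrices.
#' @param Y an `association_matrix`.
#' @param drugs character vector of drug IDs, each with exactly one `1` in
#'   `Y`; default: all such drugs.
#' @param net_cfg a [network_config()].
#' @param bal_cfg a [balance_config()] applied to the training table.
#' @param seed integer seed.
#' @param mode `"shared"` (one model, all held-out labels removed) or
#'   `"per_drug"`.
#' @param score_matrix optional m x n matrix of externally supplied scores
#'   (e.g. a ground-truth affinity oracle); when given, no model is
#'   trained.
#' @return list with `successes`, `total`, `fraction`, and a `per_drug`
#'   data frame (drug, withheld disease, rank achieved).
#' @export
new_drug_precision_at_1 <- function(UDRS, UDIS, Y, drugs = NULL,
                                    net_cfg = network_config(),
                                    bal_cfg = balance_config(),
                                    seed = 1L, mode = c("shared", "per_drug"),
                                    score_matrix = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(Y, "association_matrix"))
  singletons <- rownames(Y)[rowSums(Y) == 1]
  if (is.null(drugs)) drugs <- singletons
  bad <- setdiff(drugs, singletons)
  if (length(bad) > 0) {
    stop_fusedda(sprintf(
      "drug(s) without exactly one known association: %s",
      paste(utils::head(bad, 5), collapse = ", ")),
      "fusedda_validation_error")
  }
  if (length(drugs) == 0) {
    return(list(successes = 0L, total = 0L, fraction = NaN,
                per_drug = data.frame()))
  }
  n <- ncol(Y)
  held_out <- vapply(drugs, function(d) which(Y[d, ] == 1), 0L)

  rank_of <- function(scores, j_true) {
    # rank with ties towards the smaller index: position of j_true in the
    # ordering by (descending score, ascending index)
    ord <- order(scores, seq_along(scores),
                 decreasing = c(TRUE, FALSE), method = "radix")
    which(ord == j_true)
  }

  score_drug <- function(model, d) {
    feats <- cbind(matrix(UDRS$S[d, ], n, nrow(Y), byrow = TRUE),
                   UDIS$S)
    predict_scores(model, feats)
  }

  results <- data.frame(drug = drugs, disease = colnames(Y)[held_out],
                        rank = NA_integer_, stringsAsFactors = FALSE)

  if (!is.null(score_matrix)) {
    for (i in seq_along(drugs)) {
      results$rank[i] <- rank_of(score_matrix[drugs[i], ], held_out[i])
    }
  } else if (mode == "shared") {
    Y2 <- unclass(Y)
    Y2[drugs, ] <- 0
    Y2 <- suppressWarnings(association_matrix(Y2))
    tab <- build_pair_table(UDRS, UDIS, Y2)
    bal_cfg$seed <- seed
    tab <- smote(tab, bal_cfg)
    nc <- net_cfg
    nc$seed <- seed
    model <- train(build_model(ncol(tab$features), nc), tab, nc)
    for (i in seq_along(drugs)) {
      results$rank[i] <- rank_of(score_drug(model, drugs[i]), held_out[i])
    }
  } else {
    for (i in seq_along(drugs)) {
      Y2 <- unclass(Y)
      Y2[drugs[i], ] <- 0
      Y2 <- suppressWarnings(association_matrix(Y2))
      tab <- build_pair_table(UDRS, UDIS, Y2)
      bc <- bal_cfg
      bc$seed <- seed + i
      tab <- smote(tab, bc)
      nc <- net_cfg
      nc$seed <- seed + i
      model <- train(build_model(ncol(tab$features), nc), tab, nc)
      results$rank[i] <- rank_of(score_drug(model, drugs[i]), held_out[i])
    }
  }
  successes <- sum(results$rank == 1)
  list(successes = successes, total = length(drugs),
       fraction = successes / length(drugs), per_drug = results)
}
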