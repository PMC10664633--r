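test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1), 0.5)
  expect_identical(cc, list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))

  cc0 <- confusion_counts(c(1, 0, 1), c(0.2, 0.3, 0.9), 0)
  expect_identical(cc0$FN, 0L)
  expect_identical(cc0$TN, 0L)

  perfect <- confusion_counts(c(1, 0), c(1, 0), 0.5)
  expect_identical(perfect$FP + perfect$FN, 0L)

  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")
})

test_that("classification metrics match hand arithmetic on fixed cases", {
  cases <- list(
    list(c = list(TP = 50, TN = 40, FP = 5, FN = 5),
         want = c(0.9, 50/55, 50/55, 50/55)),
    list(c = list(TP = 10, TN = 0, FP = 10, FN = 0),
         want = c(0.5, 0.5, 1, 2/3)),
    list(c = list(TP = 0, TN = 10, FP = 0, FN = 0),
         want = c(1, 0, 0, 0)),          # degenerate denominators -> 0
    list(c = list(TP = 0, TN = 5, FP = 0, FN = 5),
         want = c(0.5, 0, 0, 0)),
    list(c = list(TP = 1, TN = 1, FP = 1, FN = 1),
         want = c(0.5, 0.5, 0.5, 0.5)),
    list(c = list(TP = 9, TN = 0, FP = 1, FN = 0),
         want = c(0.9, 0.9, 1, 2 * 0.9 / 1.9)),
    list(c = list(TP = 3, TN = 90, FP = 2, FN = 5),
         want = c(0.93, 0.6, 0.375, 2 * 0.6 * 0.375 / 0.975)),
    list(c = list(TP = 100, TN = 0, FP = 0, FN = 0),
         want = c(1, 1, 1, 1)),
    list(c = list(TP = 0, TN = 100, FP = 0, FN = 0),
         want = c(1, 0, 0, 0)),
    list(c = list(TP = 25, TN = 25, FP = 25, FN = 25),
         want = c(0.5, 0.5, 0.5, 0.5))
  )
  for (cs in cases) {
    m <- classification_metrics(cs$c)
    expect_equal(unlist(m, use.names = FALSE), cs$want, tolerance = 1e-12)
  }
})

test_that("ROC/PR areas match hand cases and handle ties by grouping", {
  perf <- curve_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), "roc")
  expect_equal(perf$auc, 1.0)
  expect_equal(curve_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), "pr")$auc, 1.0)

  const <- curve_auc(c(1, 0, 1, 0), rep(0.5, 4), "roc")
  expect_equal(const$auc, 0.5)

  mixed <- curve_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2), "roc")
  expect_equal(mixed$auc, 0.75)     # 3 of 4 (pos, neg) pairs ordered

  expect_error(curve_auc(c(1, 1), c(0.3, 0.6), "roc"), "both classes")
})

test_that("ROC area equals the Mann-Whitney oracle on random instances", {
  withr::with_seed(202, {
    for (rep in 1:50) {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      # mix of continuous and heavily tied scores
      scores <- if (rep %% 3 == 0) {
        round(runif(n), 1)
      } else {
        runif(n) + labels * runif(1, 0, 1)
      }
      got <- curve_auc(labels, scores, "roc")$auc
      expect_equal(got, oracle_auroc(labels, scores), tolerance = 1e-10)
    }
  })
})

test_that("ROC area agrees with pROC as an external cross-check", {
  skip_if_not_installed("pROC")
  withr::with_seed(44, {
    for (rep in 1:5) {
      labels <- rbinom(80, 1, 0.4)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      scores <- runif(80) + labels
      got <- curve_auc(labels, scores, "roc")$auc
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(got, ref, tolerance = 1e-10)
    }
  })
})

test_that("kfold splits are disjoint, covering, balanced and seeded", {
  f <- kfold_split(10, 5, seed = 3)
  expect_length(f, 5)
  expect_identical(sort(unlist(f)), 1:10)
  expect_true(all(lengths(f) == 2))

  f11 <- kfold_split(11, 5, seed = 3)
  expect_identical(sort(lengths(f11), decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))

  expect_identical(kfold_split(50, 5, seed = 9), kfold_split(50, 5, seed = 9))
  expect_false(identical(kfold_split(50, 5, seed = 9),
                         kfold_split(50, 5, seed = 10)))
  expect_error(kfold_split(4, 5), "k must satisfy")
})

test_that("cross-validation bookkeeping: folds partition rows, means agree", {
  fx <- small_fused_fixture(m = 10, n = 8, seed = 6)
  cfg <- network_config(hidden_layers = 1L, units_per_layer = 16L,
                        epochs = 10L, batch_size = 32L)
  rep <- cross_validate(fx$table, cfg, balance_config(k_neighbors = 3),
                        k = 5, rounds = 1, seed = 2)
  expect_identical(nrow(rep$per_fold), 5L)
  for (mc in c("accuracy", "precision", "recall", "f1")) {
    expect_equal(rep$aggregate[[mc]], mean(rep$per_fold[[mc]]),
                 tolerance = 1e-12)
  }
  # two rounds double the fold rows and reshuffle
  rep2 <- cross_validate(fx$table, cfg, balance_config(k_neighbors = 3),
                         k = 5, rounds = 2, seed = 2)
  expect_identical(nrow(rep2$per_fold), 10L)
})

test_that("new-drug ranking with an affinity oracle equals enumeration", {
  withr::with_seed(91, {
    for (rep in 1:5) {
      data <- generate_synthetic(synthetic_config(
        m = 15, n = 10, G = 3, H = 3, singleton_fraction = 0.4, seed = rep))
      Y <- data$Y
      singles <- rownames(Y)[rowSums(Y) == 1]
      fused <- fuse_views(data, snf_config(K = 4, T = 3))
      res <- new_drug_precision_at_1(fused$UDRS, fused$UDIS, Y,
                                     score_matrix = data$truth$affinity)
      # brute force: success iff the held-out disease is the first index
      # attaining the maximum affinity (ties break to the smaller index)
      want <- 0
      for (d in singles) {
        j <- which(Y[d, ] == 1)
        a <- data$truth$affinity[d, ]
        if (which(a == max(a))[1] == j) want <- want + 1
      }
      expect_identical(res$successes, as.integer(want))
      expect_identical(res$total, length(singles))
    }
  })
})

test_that("random scores rank the held-out disease first at rate 1/n", {
  n <- 20
  trials <- 1000
  withr::with_seed(500, {
    hits <- 0
    for (t in seq_len(trials)) {
      scores <- runif(n)
      j <- sample.int(n, 1)
      ord <- order(scores, seq_len(n), decreasing = c(TRUE, FALSE),
                   method = "radix")
      if (ord[1] == j) hits <- hits + 1
    }
    p <- 1 / n
    se <- sqrt(p * (1 - p) / trials)
    expect_lt(abs(hits / trials - p), 3 * se)
  })
})

test_that("a single candidate disease makes every drug succeed", {
  ids_d <- paste0("dr", 1:4); ids_i <- "di1"
  Y <- suppressWarnings(association_matrix(
    matrix(1, 4, 1, dimnames = list(ids_d, ids_i))))
  UDRS <- similarity_matrix(structure(diag(4), dimnames = list(ids_d, ids_d)),
                            "fused")
  UDIS <- similarity_matrix(structure(matrix(1, 1, 1,
                                             dimnames = list(ids_i, ids_i))),
                            "fused")
  res <- new_drug_precision_at_1(UDRS, UDIS, Y,
                                 score_matrix = matrix(0.5, 4, 1,
                                                       dimnames = list(ids_d, ids_i)))
  expect_equal(res$fraction, 1.0)
})

test_that("drugs with more than one association are rejected from the cohort", {
  fx <- small_fused_fixture(m = 8, n = 6, seed = 13)
  multi <- rownames(fx$data$Y)[rowSums(fx$data$Y) > 1][1]
  skip_if(is.na(multi))
  expect_error(
    new_drug_precision_at_1(fx$fused$UDRS, fx$fused$UDIS, fx$data$Y,
                            drugs = multi,
                            score_matrix = fx$data$truth$affinity),
    "exactly one")
})
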