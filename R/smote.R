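# SMOTE class balancing. Known associations and non-associations are
# imbalanced; new minority-class rows are interpolated between a minority
# row and one of its k nearest minority neighbours until the
# minority/majority count ratio reaches the configured balance rate
# (default 0.9). The minority class is detected from the data rather than
# hard-coded, since synthetic datasets may invert the imbalance.

#' SMOTE balancing parameters
#'
#' @param target_ratio minority/majority count ratio to reach, in `(0, 1]`.
#'   Default 0.9 (the balance rate).
#' @param k_neighbors neighbour pool size for interpolation; must be
#'   smaller than the minority class. Default 5.
#' @param seed integer seed making the oversampling reproducible.
#' @return an object of class `balance_config`.
#' @export
balance_config <- function(target_ratio = 0.9, k_neighbors = 5L, seed = 1L) {
  if (target_ratio <= 0 || target_ratio > 1) {
    stop_fusedda("target_ratio must lie in (0, 1]", "fusedda_parameter_error")
  }
  if (k_neighbors < 1) {
    stop_fusedda("k_neighbors must be >= 1", "fusedda_parameter_error")
  }
  structure(list(target_ratio = target_ratio,
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "balance_config")
}

#' Number of synthetic minority rows needed for a balance rate
#'
#' `max(0, ceiling(ratio * n_majority) - n_minority)`: the smallest count
#' of appended rows after which minority/majority >= ratio.
#'
#' @param n_minority,n_majority class counts.
#' @param ratio target minority/majority ratio.
#' @return integer count of synthetic rows to create.
#' @export
minority_target_count <- function(n_minority, n_majority, ratio = 0.9) {
  stopifnot(n_minority >= 0, n_majority >= 0, ratio > 0, ratio <= 1)
  max(0L, as.integer(ceiling(ratio * n_majority) - n_minority))
}

#' Balance a pair table by SMOTE oversampling
#'
#' Appends synthetic minority rows `x + lambda * (x_nn - x)` where `x` is a
#' uniformly chosen minority row, `x_nn` one of its `k_neighbors` nearest
#' minority neighbours (Euclidean distance, ties towards the smaller
#' index) and `lambda ~ Uniform(0, 1)`. Observed rows are never modified
#' or dropped; synthetic rows carry `provenance = "synthetic"` and the
#' minority label. Deterministic for a fixed `cfg$seed`.
#'
#' @param table a `pair_table` with both classes present.
#' @param cfg a [balance_config()].
#' @return the augmented `pair_table`.
#' @export
smote <- function(table, cfg = balance_config()) {
  stopifnot(inherits(table, "pair_table"))
  n1 <- sum(table$label == 1)
  n0 <- sum(table$label == 0)
  if (n1 == 0 || n0 == 0) {
    stop_fusedda("minority class empty: both classes must be present",
                 "fusedda_validation_error")
  }
  minority_label <- if (n1 <= n0) 1 else 0
  n_min <- min(n1, n0)
  n_maj <- max(n1, n0)
  if (n_min <= cfg$k_neighbors) {
    stop_fusedda(sprintf(
      "minority class size (%d) must exceed k_neighbors (%d)",
      n_min, cfg$k_neighbors), "fusedda_parameter_error")
  }
  n_new <- minority_target_count(n_min, n_maj, cfg$target_ratio)
  if (n_new == 0) return(table)

  min_idx <- which(table$label == minority_label)
  X <- table$features[min_idx, , drop = FALSE]

  # k nearest minority neighbours per minority row, self excluded,
  # ties broken towards the smaller index
  D <- as.matrix(stats::dist(X))
  k <- cfg$k_neighbors
  nn <- matrix(0L, nrow(X), k)
  for (i in seq_len(nrow(X))) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_along(d), method = "radix")
    nn[i, ] <- ord[seq_len(k)]
  }

  synth <- withr::with_seed(cfg$seed, {
    parents <- sample.int(nrow(X), n_new, replace = TRUE)
    nb_pick <- sample.int(k, n_new, replace = TRUE)
    lambda <- stats::runif(n_new)
    x <- X[parents, , drop = FALSE]
    xn <- X[nn[cbind(parents, nb_pick)], , drop = FALSE]
    x + lambda * (xn - x)
  })
  colnames(synth) <- colnames(table$features)

  structure(list(
    drug = c(table$drug, rep(NA_character_, n_new)),
    disease = c(table$disease, rep(NA_character_, n_new)),
    label = c(table$label, rep(minority_label, n_new)),
    features = rbind(table$features, synth),
    provenance = c(table$provenance, rep("synthetic", n_new)),
    m = table$m, n = table$n
  ), class = "pair_table")
}
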