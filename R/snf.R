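# Similarity network fusion: merge several similarity matrices over the
# same entities into one by iterative cross-diffusion. Each view v carries
# a full-kernel status matrix P^(v) (row-stochastic, half the mass on the
# diagonal) and a sparse KNN local kernel S^(v); at every step the local
# kernel of one view diffuses the average status of the other views:
#
#   P^(v) <- S^(v) %*% mean_{u != v} P^(u) %*% t(S^(v))
#
# followed by symmetrization and re-normalization. The fused matrix is the
# average of the view status matrices after T steps.

#' SNF hyperparameters
#'
#' @param K neighbour count for the local kernel (clamped to `m - 1` for
#'   small problems at fusion time). Default 20.
#' @param T diffusion iteration count. Default 20. `T = 0` returns the mean
#'   of the full-kernel-normalized views.
#' @param convergence_tol optional early-stop threshold on the maximum
#'   absolute change of any status entry between iterations; `0` disables
#'   early stopping.
#' @param renormalize re-apply full-kernel normalization after every
#'   iteration (default `TRUE`); `FALSE` gives the drifting variant.
#' @return an object of class `snf_config`.
#' @export
snf_config <- function(K = 20L, T = 20L, convergence_tol = 0,
                       renormalize = TRUE) {
  if (K < 1) stop_fusedda("K must be >= 1", "fusedda_parameter_error")
  if (T < 0) stop_fusedda("T must be >= 0", "fusedda_parameter_error")
  if (convergence_tol < 0) {
    stop_fusedda("convergence_tol must be >= 0", "fusedda_parameter_error")
  }
  structure(list(K = as.integer(K), T = as.integer(T),
                 convergence_tol = convergence_tol,
                 renormalize = isTRUE(renormalize)),
            class = "snf_config")
}

#' Full-kernel row normalization
#'
#' Maps a symmetric non-negative similarity matrix to a row-stochastic
#' status matrix that keeps half the probability mass on the diagonal:
#' `P[i, j] = W[i, j] / (2 * sum_{k != i} W[i, k])` off-diagonal and
#' `P[i, i] = 1/2`. An entity with zero off-diagonal mass (isolated) keeps
#' all its mass on the diagonal and a warning is raised.
#'
#' @param W square symmetric non-negative matrix (or `similarity_matrix`).
#' @return a row-stochastic matrix of the same shape.
#' @export
full_kernel_normalize <- function(W) {
  if (inherits(W, "similarity_matrix")) W <- W$S
  W <- as.matrix(W)
  off <- rowSums(W) - diag(W)
  P <- W / (2 * off)          # recycled column-wise over rows
  diag(P) <- 0.5
  iso <- which(off <= 0)
  if (length(iso) > 0) {
    warning(sprintf("isolated entit%s (zero off-diagonal similarity): %s",
                    if (length(iso) == 1) "y" else "ies",
                    paste(utils::head(iso, 5), collapse = ", ")))
    P[iso, ] <- 0
    P[cbind(iso, iso)] <- 1
  }
  P
}

#' KNN local kernel
#'
#' For each entity keeps only its `K` most similar neighbours (self
#' excluded, ties broken towards the smaller index) and renormalizes over
#' them, encoding the assumption that local similarities are the reliable
#' ones.
#'
#' @param W square symmetric non-negative matrix (or `similarity_matrix`).
#' @param K neighbour count, `1 <= K < nrow(W)`.
#' @return a row-normalized sparse local matrix (zero outside each row's
#'   neighbour set).
#' @export
knn_kernel <- function(W, K) {
  if (inherits(W, "similarity_matrix")) W <- W$S
  W <- as.matrix(W)
  m <- nrow(W)
  if (K < 1 || K >= m) {
    stop_fusedda(sprintf("K must satisfy 1 <= K < %d (got %s)", m, K),
                 "fusedda_parameter_error")
  }
  S <- matrix(0, m, m, dimnames = dimnames(W))
  for (i in seq_len(m)) {
    w <- W[i, ]
    w[i] <- -Inf                       # self never a neighbour
    ord <- order(w, seq_len(m), decreasing = c(TRUE, FALSE), method = "radix")
    nb <- ord[seq_len(K)]
    tot <- sum(W[i, nb])
    if (tot > 0) S[i, nb] <- W[i, nb] / tot
  }
  S
}

#' Fuse similarity matrices by cross-diffusion
#'
#' Produces the unified drug similarity (UDRS, from the three drug views)
#' or unified disease similarity (UDIS, from the two disease views). With a
#' single view, returns its full-kernel-normalized symmetrized form. The
#' result is deterministic for fixed inputs and configuration; the per-
#' iteration maximum status change is recorded in the `"trace"` attribute
#' of the returned matrix.
#'
#' @param views list of `similarity_matrix` objects (or plain symmetric
#'   matrices) over an identical entity set, in identical order.
#' @param cfg an [snf_config()].
#' @return a `similarity_matrix` of kind `"fused"`.
#' @export
snf <- function(views, cfg = snf_config()) {
  stopifnot(length(views) >= 1)
  mats <- lapply(views, function(v) if (inherits(v, "similarity_matrix")) v$S else as.matrix(v))
  ids <- rownames(mats[[1]])
  for (M in mats) {
    if (!identical(dim(M), dim(mats[[1]])) ||
        (!is.null(ids) && !identical(rownames(M), ids))) {
      stop_fusedda("views must share one entity index (same IDs, same order)",
                   "fusedda_alignment_error")
    }
  }
  m <- nrow(mats[[1]])
  V <- length(mats)

  if (V == 1) {
    P <- full_kernel_normalize(mats[[1]])
    P <- (P + t(P)) / 2
    out <- similarity_matrix(structure(P, dimnames = list(ids, ids)), "fused")
    attr(out, "trace") <- numeric(0)
    return(out)
  }

  K <- min(cfg$K, m - 1L)
  P <- lapply(mats, full_kernel_normalize)
  S <- lapply(mats, knn_kernel, K = K)
  trace <- numeric(0)

  if (cfg$T > 0) {
    for (t in seq_len(cfg$T)) {
      sumP <- Reduce(`+`, P)
      newP <- vector("list", V)
      for (v in seq_len(V)) {
        meanOthers <- (sumP - P[[v]]) / (V - 1)
        Pv <- S[[v]] %*% meanOthers %*% t(S[[v]])
        Pv <- (Pv + t(Pv)) / 2
        if (cfg$renormalize) {
          Pv <- suppressWarnings(full_kernel_normalize(Pv))
          Pv <- (Pv + t(Pv)) / 2
        }
        newP[[v]] <- Pv
      }
      delta <- max(vapply(seq_len(V),
                          function(v) max(abs(newP[[v]] - P[[v]])), 0))
      trace <- c(trace, delta)
      P <- newP
      if (cfg$convergence_tol > 0 && delta < cfg$convergence_tol) break
    }
  }

  fused <- Reduce(`+`, P) / V
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  out <- similarity_matrix(fused, kind = "fused")
  attr(out, "trace") <- trace
  out
}
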