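# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, no vectorization) and share no code
# with the package internals.

# cosine similarity matrix by double loop
oracle_cosine_matrix <- function(X) {
  m <- nrow(X)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) {
        S[i, j] <- 1
      } else {
        ni <- sqrt(sum(X[i, ]^2))
        nj <- sqrt(sum(X[j, ]^2))
        S[i, j] <- if (ni == 0 || nj == 0) 0 else sum(X[i, ] * X[j, ]) / (ni * nj)
      }
    }
  }
  S
}

# naive matrix product by triple loop
oracle_matmul <- function(A, B) {
  m <- nrow(A); p <- ncol(A); n <- ncol(B)
  C <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(p)) acc <- acc + A[i, k] * B[k, j]
      C[i, j] <- acc
    }
  }
  C
}

oracle_full_kernel <- function(W) {
  m <- nrow(W)
  P <- matrix(0, m, m)
  for (i in seq_len(m)) {
    off <- 0
    for (k in seq_len(m)) if (k != i) off <- off + W[i, k]
    if (off <= 0) {
      P[i, i] <- 1
    } else {
      for (j in seq_len(m)) P[i, j] <- if (j == i) 0.5 else W[i, j] / (2 * off)
    }
  }
  P
}

oracle_knn <- function(W, K) {
  m <- nrow(W)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) {
    cand <- setdiff(seq_len(m), i)
    # selection sort by (similarity desc, index asc)
    nb <- integer(0)
    remaining <- cand
    for (k in seq_len(K)) {
      best <- remaining[1]
      for (j in remaining) {
        if (W[i, j] > W[i, best]) best <- j
      }
      nb <- c(nb, best)
      remaining <- setdiff(remaining, best)
    }
    tot <- sum(W[i, nb])
    if (tot > 0) for (j in nb) S[i, j] <- W[i, j] / tot
  }
  S
}

# naive SNF cross-diffusion following the same update rules
oracle_snf <- function(views, K, T, renormalize = TRUE) {
  V <- length(views)
  m <- nrow(views[[1]])
  if (V == 1) {
    P <- oracle_full_kernel(views[[1]])
    return((P + t(P)) / 2)
  }
  P <- lapply(views, oracle_full_kernel)
  S <- lapply(views, oracle_knn, K = K)
  if (T > 0) {
    for (t in seq_len(T)) {
      newP <- vector("list", V)
      for (v in seq_len(V)) {
        meanOthers <- matrix(0, m, m)
        for (u in seq_len(V)) {
          if (u != v) meanOthers <- meanOthers + P[[u]]
        }
        meanOthers <- meanOthers / (V - 1)
        Pv <- oracle_matmul(oracle_matmul(S[[v]], meanOthers), t(S[[v]]))
        Pv <- (Pv + t(Pv)) / 2
        if (renormalize) {
          Pv <- oracle_full_kernel(Pv)
          Pv <- (Pv + t(Pv)) / 2
        }
        newP[[v]] <- Pv
      }
      P <- newP
    }
  }
  out <- matrix(0, m, m)
  for (v in seq_len(V)) out <- out + P[[v]]
  out <- out / V
  (out + t(out)) / 2
}

# AUROC as the Mann-Whitney pair-counting statistic
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# random symmetric non-negative similarity matrix with unit diagonal
random_similarity <- function(m) {
  W <- matrix(runif(m * m), m, m)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

# a minimal pair_table wrapper around an arbitrary feature matrix, for
# classifier tests that do not need the full pipeline
make_table <- function(X, y) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(drug = as.character(seq_along(y)),
                 disease = as.character(seq_along(y)),
                 label = y,
                 features = X,
                 provenance = rep("observed", length(y)),
                 m = NA_integer_, n = NA_integer_),
            class = "pair_table")
}

# two separable Gaussian blobs, n rows total
blob_table <- function(n = 400, d = 10, sep = 3, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    X[y == 1, 1:2] <- X[y == 1, 1:2] + sep
    make_table(X, y)
  })
}

# small fused-similarity fixture shared by table/evaluation tests
small_fused_fixture <- function(m = 12, n = 9, seed = 11) {
  data <- generate_synthetic(synthetic_config(m = m, n = n, G = min(3, m),
                                              H = min(3, n), seed = seed))
  fused <- fuse_views(data, snf_config(K = 4, T = 5))
  list(data = data, fused = fused,
       table = build_pair_table(fused$UDRS, fused$UDIS, data$Y))
}
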