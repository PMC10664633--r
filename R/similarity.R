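# Cosine similarity on binary feature profiles. Binary fingerprints are
# long and sparse, so the angle between profile vectors is the natural
# match score: 1 for identical direction, 0 for orthogonal (no shared bits).

#' Cosine similarity between two non-negative vectors
#'
#' `cosine(x, y) = (x . y) / (||x|| ||y||)`. For non-negative input the
#' value lies in `[0, 1]`. An all-zero vector carries no evidence, so its
#' similarity to anything is defined as 0.
#'
#' @param x,y numeric vectors of equal length, finite and non-negative.
#' @return a scalar in `[0, 1]`.
#' @export
#' @examples
#' cosine(c(1, 1, 0), c(1, 0, 0))  # 1 / sqrt(2)
cosine <- function(x, y) {
  if (length(x) != length(y)) {
    stop_fusedda("cosine: vectors differ in length", "fusedda_dimension_error")
  }
  if (any(is.na(x)) || any(is.na(y)) || any(!is.finite(c(x, y)))) {
    stop_fusedda("cosine: entries must be finite and non-missing",
                 "fusedda_validation_error")
  }
  if (any(x < 0) || any(y < 0)) {
    stop_fusedda("cosine: entries must be non-negative",
                 "fusedda_validation_error")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  min(1, sum(x * y) / (nx * ny))
}

#' Per-view similarity matrix from a feature profile
#'
#' Applies [cosine()] to every pair of entity rows. The diagonal is forced
#' to exactly 1 (an entity is maximally similar to itself, including
#' entities with empty profiles) and all-zero rows get off-diagonal
#' similarity 0, so downstream normalization never divides by a profile
#' norm of zero.
#'
#' @param P a `feature_profile`.
#' @return a `similarity_matrix` of kind `"raw"`.
#' @export
profile_to_similarity <- function(P) {
  stopifnot(inherits(P, "feature_profile"))
  X <- P$values
  if (nrow(X) < 1) {
    stop_fusedda("profile has no entities", "fusedda_validation_error")
  }
  nrm <- sqrt(rowSums(X^2))
  G <- tcrossprod(X)                    # X %*% t(X)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, G / denom, 0)
  S <- pmin(S, 1)                       # clip float jitter above 1
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  similarity_matrix(S, kind = "raw")
}
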