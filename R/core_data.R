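#' @keywords internal
"_PACKAGE"

# ---- internal validation helpers ------------------------------------------

stop_fusedda <- function(msg, class) {
  stop(structure(class = c(class, "fusedda_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_no_duplicates <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_fusedda(sprintf("duplicate %s ID(s): %s", what,
                         paste(unique(dup), collapse = ", ")),
                 "fusedda_validation_error")
  }
  invisible(ids)
}

VIEW_NAMES <- c("chemical_structure", "side_effect", "drug_target",
                "phenotype", "disease_target")

# ---- feature profiles ------------------------------------------------------

#' Construct a binary feature profile
#'
#' A feature profile is one "view" of an entity class: a binary entity x
#' feature matrix, e.g. drugs x chemical-substructure bits or diseases x
#' phenotype terms. Row names are the entity IDs, column names the feature
#' IDs; both orders are preserved throughout a pipeline run.
#'
#' @param values numeric matrix with entries in `{0, 1}`, row names = entity
#'   IDs, column names = feature IDs.
#' @param view_name one of `"chemical_structure"`, `"side_effect"`,
#'   `"drug_target"`, `"phenotype"`, `"disease_target"`.
#' @return an object of class `feature_profile`.
#' @export
feature_profile <- function(values, view_name) {
  view_name <- match.arg(view_name, VIEW_NAMES)
  values <- as.matrix(values)
  if (ncol(values) == 0) {
    stop_fusedda("no features: profile has zero feature columns",
                 "fusedda_validation_error")
  }
  if (is.null(rownames(values))) {
    stop_fusedda("profile matrix must carry entity IDs as row names",
                 "fusedda_validation_error")
  }
  check_no_duplicates(rownames(values), "entity")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop_fusedda(sprintf(
      "non-binary cell at row '%s', column '%s': %s",
      rownames(values)[i],
      if (is.null(colnames(values))) j else colnames(values)[j],
      format(values[i, j])), "fusedda_parse_error")
  }
  storage.mode(values) <- "double"
  structure(list(values = values, view_name = view_name),
            class = "feature_profile")
}

#' Read a binary feature profile from CSV/TSV
#'
#' Expects a header row of feature IDs and a first column of entity IDs;
#' every data cell must be 0 or 1.
#'
#' @param path file path.
#' @param view_name view label, see [feature_profile()].
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return a `feature_profile`.
#' @export
read_binary_profile <- function(path, view_name, sep = ",") {
  if (!file.exists(path)) {
    stop_fusedda(sprintf("file not found: %s", path), "fusedda_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) {
    stop_fusedda("no features: file has an ID column but no feature columns",
                 "fusedda_validation_error")
  }
  ids <- df[[1]]
  check_no_duplicates(ids, "entity")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(num)) + 1
    j <- ((bad[1] - 1) %/% nrow(num)) + 1
    stop_fusedda(sprintf(
      "non-binary cell at row '%s', column '%s': '%s'",
      ids[i], colnames(num)[j], vals[i, j]), "fusedda_parse_error")
  }
  feature_profile(num, view_name)
}

#' @export
print.feature_profile <- function(x, ...) {
  cat(sprintf("<feature_profile '%s': %d entities x %d features, density %.3f>\n",
              x$view_name, nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

# ---- association matrix ----------------------------------------------------

#' Construct a drug x disease association matrix
#'
#' @param Y binary matrix, row names = drug IDs, column names = disease IDs.
#'   `Y[i, j] == 1` states that drug i is indicated for disease j.
#' @return an object of class `association_matrix` (the validated matrix).
#' @export
association_matrix <- function(Y) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y)) || is.null(colnames(Y))) {
    stop_fusedda("association matrix needs drug row names and disease column names",
                 "fusedda_validation_error")
  }
  check_no_duplicates(rownames(Y), "drug")
  check_no_duplicates(colnames(Y), "disease")
  if (any(is.na(Y)) || !all(Y %in% c(0, 1))) {
    stop_fusedda("association matrix entries must all be 0 or 1",
                 "fusedda_validation_error")
  }
  storage.mode(Y) <- "double"
  if (sum(Y) == 0) {
    warning("association matrix contains no known associations (all zero)")
  }
  structure(Y, class = c("association_matrix", "matrix", "array"))
}

#' Read a drug x disease association matrix from CSV/TSV
#'
#' Header row carries disease IDs, first column carries drug IDs, cells are
#' 0/1. Ragged rows are a format error.
#'
#' @inheritParams read_binary_profile
#' @return an `association_matrix`.
#' @export
read_association_matrix <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop_fusedda(sprintf("file not found: %s", path), "fusedda_io_error")
  }
  n_fields <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(n_fields)) != 1) {
    stop_fusedda("ragged rows: not all lines have the same number of fields",
                 "fusedda_format_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  if (any(is.na(num)) || !all(num %in% c(0, 1))) {
    stop_fusedda("association matrix entries must all be 0 or 1",
                 "fusedda_validation_error")
  }
  association_matrix(num)
}

# ---- similarity matrices ---------------------------------------------------

#' Construct a similarity matrix over one entity class
#'
#' Raw (per-view cosine) matrices have entries in `[0, 1]` and unit
#' diagonal; fused matrices (the SNF output) are non-negative, finite and
#' symmetric but not rescaled.
#'
#' @param S square numeric matrix with matching row/column entity names.
#' @param kind `"raw"` or `"fused"`.
#' @return an object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(S, kind = c("raw", "fused")) {
  kind <- match.arg(kind)
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) {
    stop_fusedda("similarity matrix must be square", "fusedda_validation_error")
  }
  if (is.null(rownames(S))) {
    stop_fusedda("similarity matrix must carry entity IDs as dimnames",
                 "fusedda_validation_error")
  }
  if (is.null(colnames(S))) colnames(S) <- rownames(S)
  if (!identical(rownames(S), colnames(S))) {
    stop_fusedda("row and column entity IDs must match",
                 "fusedda_validation_error")
  }
  check_no_duplicates(rownames(S), "entity")
  if (any(!is.finite(S))) {
    stop_fusedda("similarity entries must be finite", "fusedda_validation_error")
  }
  if (max(abs(S - t(S))) > 1e-9) {
    stop_fusedda("similarity matrix is not symmetric (tolerance 1e-9)",
                 "fusedda_validation_error")
  }
  if (any(S < 0)) {
    stop_fusedda("similarity entries must be non-negative",
                 "fusedda_validation_error")
  }
  if (kind == "raw") {
    if (any(S > 1)) {
      stop_fusedda("raw similarity entries must lie in [0, 1]",
                   "fusedda_validation_error")
    }
    if (any(abs(diag(S) - 1) > 1e-12)) {
      stop_fusedda("raw similarity diagonal must equal 1",
                   "fusedda_validation_error")
    }
  }
  structure(list(S = S, kind = kind), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix (%s): %d x %d entities>\n",
              x$kind, nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Write a similarity matrix to CSV
#'
#' Entries are serialized with 12 significant digits; symmetry is checked
#' before anything is written.
#'
#' @param S a `similarity_matrix`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_similarity <- function(S, path, sep = ",") {
  stopifnot(inherits(S, "similarity_matrix"))
  M <- S$S
  if (max(abs(M - t(M))) > 1e-9) {
    stop_fusedda("refusing to write asymmetric similarity matrix",
                 "fusedda_validation_error")
  }
  df <- data.frame(id = rownames(M),
                   signif(M, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(M))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a similarity matrix from CSV
#'
#' @param path input file path.
#' @param kind `"raw"` or `"fused"`, see [similarity_matrix()].
#' @param sep field separator.
#' @return a `similarity_matrix`.
#' @export
read_similarity <- function(path, kind = c("raw", "fused"), sep = ",") {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- ids
  # symmetrize away formatting jitter well below the 1e-9 contract
  M <- (M + t(M)) / 2
  similarity_matrix(M, kind = kind)
}

#' Align feature profiles to the association matrix entity order
#'
#' The association matrix defines the canonical drug and disease order for a
#' run. Profiles are re-indexed to that order; a profile entity absent from
#' the association matrix, or vice versa, is an error.
#'
#' @param profiles list of `feature_profile`s over the same entity class.
#' @param ids character vector of canonical entity IDs (row or column names
#'   of the association matrix).
#' @return the list of profiles, rows reordered to `ids`.
#' @export
align_profiles <- function(profiles, ids) {
  lapply(profiles, function(p) {
    have <- rownames(p$values)
    extra <- setdiff(have, ids)
    if (length(extra) > 0) {
      stop_fusedda(sprintf(
        "profile '%s' contains entities absent from the association matrix: %s",
        p$view_name, paste(utils::head(extra, 5), collapse = ", ")),
        "fusedda_alignment_error")
    }
    missing <- setdiff(ids, have)
    if (length(missing) > 0) {
      stop_fusedda(sprintf(
        "profile '%s' is missing entities: %s",
        p$view_name, paste(utils::head(missing, 5), collapse = ", ")),
        "fusedda_alignment_error")
    }
    p$values <- p$values[ids, , drop = FALSE]
    p
  })
}
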