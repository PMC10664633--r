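# The pair feature table F: one row per (drug, disease) pair in drug-major
# order. Each row's feature vector is the drug's row of the fused drug
# similarity (UDRS) concatenated with the disease's row of the fused
# disease similarity (UDIS), so a pair is described by how its drug relates
# to every drug and how its disease relates to every disease. Counting the
# two ID columns and the label, the exported table has m + n + 3 columns.

#' Build the pair feature table
#'
#' @param UDRS fused drug `similarity_matrix` (m x m), entities equal to
#'   the association matrix row names.
#' @param UDIS fused disease `similarity_matrix` (n x n), entities equal to
#'   the association matrix column names.
#' @param Y an `association_matrix` (m x n).
#' @return an object of class `pair_table` with fields `drug`, `disease`
#'   (character, length m*n), `label` (0/1), `features` (m*n x (m+n)
#'   matrix, columns `dr_1..dr_m, di_1..di_n`), and `provenance`
#'   (`"observed"` for every row; SMOTE appends `"synthetic"` rows).
#' @export
build_pair_table <- function(UDRS, UDIS, Y) {
  stopifnot(inherits(UDRS, "similarity_matrix"),
            inherits(UDIS, "similarity_matrix"),
            inherits(Y, "association_matrix"))
  drugs <- rownames(Y)
  diseases <- colnames(Y)
  if (!identical(rownames(UDRS$S), drugs)) {
    stop_fusedda("UDRS entity index does not match the association matrix drugs",
                 "fusedda_alignment_error")
  }
  if (!identical(rownames(UDIS$S), diseases)) {
    stop_fusedda("UDIS entity index does not match the association matrix diseases",
                 "fusedda_alignment_error")
  }
  m <- length(drugs)
  n <- length(diseases)
  # drug-major enumeration: all diseases for drug 1, then drug 2, ...
  di <- rep(seq_len(m), each = n)
  dj <- rep(seq_len(n), times = m)
  features <- cbind(UDRS$S[di, , drop = FALSE], UDIS$S[dj, , drop = FALSE])
  colnames(features) <- c(paste0("dr_", seq_len(m)), paste0("di_", seq_len(n)))
  rownames(features) <- NULL
  structure(list(
    drug = drugs[di],
    disease = diseases[dj],
    label = as.numeric(t(Y)),          # t(Y) unrolls drug-major
    features = features,
    provenance = rep("observed", m * n),
    m = m, n = n
  ), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf(
    "<pair_table: %d rows (%d observed, %d synthetic), %d features, %d positive>\n",
    length(x$label), sum(x$provenance == "observed"),
    sum(x$provenance == "synthetic"), ncol(x$features), sum(x$label == 1)))
  invisible(x)
}

#' Subset a pair table by row indices
#'
#' @param table a `pair_table`.
#' @param idx integer row indices.
#' @return the subsetted `pair_table`.
#' @export
pair_table_subset <- function(table, idx) {
  structure(list(
    drug = table$drug[idx],
    disease = table$disease[idx],
    label = table$label[idx],
    features = table$features[idx, , drop = FALSE],
    provenance = table$provenance[idx],
    m = table$m, n = table$n
  ), class = "pair_table")
}

#' Export a pair table as CSV
#'
#' Columns: `drug, disease, interaction, dr_1..dr_m, di_1..di_n`, plus a
#' trailing `provenance` column flagging SMOTE rows.
#'
#' @param table a `pair_table`.
#' @param path output file path.
#' @export
write_pair_table <- function(table, path) {
  df <- data.frame(drug = table$drug, disease = table$disease,
                   interaction = table$label,
                   table$features,
                   provenance = table$provenance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
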