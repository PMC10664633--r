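# End-to-end orchestration: similarity -> fusion -> pair table ->
# cross-validated training -> reports, plus the optional new-drug ranking
# and full-matrix candidate scoring, all driven by one YAML config with
# named seeds so a run is reproducible from a single file.

#' Assemble a run configuration
#'
#' Exactly one of `input_paths` (named list with `chemical_structure`,
#' `side_effect`, `drug_target`, `phenotype`, `disease_target`,
#' `associations`) or `synthetic` (a [synthetic_config()]) must be given.
#'
#' @param input_paths named list of the five profile CSVs plus the
#'   association CSV, or `NULL`.
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param snf an [snf_config()].
#' @param balance a [balance_config()].
#' @param network a [network_config()].
#' @param k,rounds cross-validation settings.
#' @param seed master seed for evaluation.
#' @param new_drug run the new-drug ranking experiment.
#' @param predict_unknowns train on all known associations and rank every
#'   unknown pair per disease (comprehensive-prediction mode).
#' @param out_dir output directory for run artifacts.
#' @param sep field separator for the input files.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_paths = NULL, synthetic = NULL,
                       snf = snf_config(), balance = balance_config(),
                       network = network_config(), k = 5L, rounds = 1L,
                       seed = 1L, new_drug = FALSE,
                       predict_unknowns = FALSE, out_dir = tempfile("fusedda_"),
                       sep = ",") {
  if (is.null(input_paths) == is.null(synthetic)) {
    stop_fusedda("exactly one of input_paths or synthetic must be given",
                 "fusedda_config_error")
  }
  structure(list(input_paths = input_paths, synthetic = synthetic,
                 snf = snf, balance = balance, network = network,
                 k = as.integer(k), rounds = as.integer(rounds),
                 seed = as.integer(seed), new_drug = isTRUE(new_drug),
                 predict_unknowns = isTRUE(predict_unknowns),
                 out_dir = out_dir, sep = sep),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; nested sections
#' `snf`, `balance`, `network`, `synthetic` override the corresponding
#' config defaults field-wise.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fill <- function(ctor, lst) {
    if (is.null(lst)) return(do.call(ctor, list()))
    # YAML 1.1 reads a bare `n:` key as a boolean; map it back
    names(lst)[names(lst) %in% c("FALSE", "no")] <- "n"
    names(lst)[names(lst) %in% c("TRUE", "yes")] <- "y"
    do.call(ctor, lst)
  }
  run_config(
    input_paths = y$input_paths,
    synthetic = if (!is.null(y$synthetic)) fill(synthetic_config, y$synthetic),
    snf = fill(snf_config, y$snf),
    balance = fill(balance_config, y$balance),
    network = fill(network_config, y$network),
    k = y$k %||% 5L, rounds = y$rounds %||% 1L, seed = y$seed %||% 1L,
    new_drug = isTRUE(y$new_drug),
    predict_unknowns = isTRUE(y$predict_unknowns),
    out_dir = y$out_dir %||% tempfile("fusedda_"),
    sep = y$sep %||% ","
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: load or generate the five profiles + Y per the config
load_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    data <- generate_synthetic(cfg$synthetic)
    return(list(drug_profiles = data$drug_profiles,
                disease_profiles = data$disease_profiles,
                Y = data$Y, truth = data$truth))
  }
  p <- cfg$input_paths
  Y <- read_association_matrix(p$associations, sep = cfg$sep)
  dviews <- c("chemical_structure", "side_effect", "drug_target")
  iviews <- c("phenotype", "disease_target")
  drug_profiles <- lapply(dviews, function(v) {
    read_binary_profile(p[[v]], v, sep = cfg$sep)
  })
  names(drug_profiles) <- dviews
  disease_profiles <- lapply(iviews, function(v) {
    read_binary_profile(p[[v]], v, sep = cfg$sep)
  })
  names(disease_profiles) <- iviews
  list(drug_profiles = align_profiles(drug_profiles, rownames(Y)),
       disease_profiles = align_profiles(disease_profiles, colnames(Y)),
       Y = Y, truth = NULL)
}

#' Fuse the drug and disease views of a loaded dataset
#'
#' Convenience wrapper: cosine similarity per view, then SNF per side.
#'
#' @param inputs list with `drug_profiles`, `disease_profiles` (see
#'   [generate_synthetic()]).
#' @param snf_cfg an [snf_config()].
#' @return list with `UDRS` and `UDIS` fused `similarity_matrix` objects.
#' @export
fuse_views <- function(inputs, snf_cfg = snf_config()) {
  drs <- lapply(inputs$drug_profiles, profile_to_similarity)
  dis <- lapply(inputs$disease_profiles, profile_to_similarity)
  list(UDRS = snf(drs, snf_cfg), UDIS = snf(dis, snf_cfg))
}

#' Run the full pipeline
#'
#' Executes similarity calculation, two-step SNF fusion, pair-table
#' construction, repeated cross-validation (SMOTE confined to training
#' folds), and optionally the new-drug ranking experiment and
#' comprehensive prediction of unknown pairs. All artifacts (UDRS, UDIS,
#' the pair table, metrics JSON, ROC/PR curve CSVs, ranked candidates and
#' a run log) are written under `cfg$out_dir`; a re-run with the same
#' config reproduces them exactly.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the evaluation report, the fused
#'   matrices and the artifact directory.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat("", file = log_path)  # truncate
  logf("seeds: master=%d smote=%d network=%d", cfg$seed, cfg$balance$seed,
       cfg$network$seed)

  inputs <- load_inputs(cfg)
  logf("data: %d drugs x %d diseases, %d known associations",
       nrow(inputs$Y), ncol(inputs$Y), sum(inputs$Y))

  fused <- fuse_views(inputs, cfg$snf)
  write_similarity(fused$UDRS, file.path(cfg$out_dir, "UDRS.csv"))
  write_similarity(fused$UDIS, file.path(cfg$out_dir, "UDIS.csv"))
  tr_drug <- attr(fused$UDRS, "trace")
  tr_dis <- attr(fused$UDIS, "trace")
  logf("snf: UDRS %d iterations (final max dP %.3e); UDIS %d iterations (final max dP %.3e)",
       length(tr_drug), if (length(tr_drug)) tr_drug[length(tr_drug)] else NA,
       length(tr_dis), if (length(tr_dis)) tr_dis[length(tr_dis)] else NA)

  table <- build_pair_table(fused$UDRS, fused$UDIS, inputs$Y)
  write_pair_table(table, file.path(cfg$out_dir, "pair_table.csv"))

  n1 <- sum(table$label == 1); n0 <- sum(table$label == 0)
  tc <- minority_target_count(min(n1, n0), max(n1, n0),
                              cfg$balance$target_ratio)
  logf("classes: %d positive / %d negative; SMOTE will add %d rows per full table (achieved ratio %.4f)",
       n1, n0, tc, (min(n1, n0) + tc) / max(n1, n0))

  report <- cross_validate(table, cfg$network, cfg$balance, k = cfg$k,
                           rounds = cfg$rounds, seed = cfg$seed)
  metrics <- list(aggregate = report$aggregate,
                  dispersion = report$dispersion,
                  per_fold = report$per_fold)
  for (i in seq_len(nrow(report$per_fold))) {
    r <- report$per_fold[i, ]
    logf("fold r%d f%d: acc %.4f prec %.4f rec %.4f f1 %.4f auroc %.4f aupr %.4f",
         r$round, r$fold, r$accuracy, r$precision, r$recall, r$f1,
         r$auroc, r$aupr)
  }
  if (!is.null(report$curves)) {
    utils::write.csv(report$curves$roc,
                     file.path(cfg$out_dir, "roc_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(report$curves$pr,
                     file.path(cfg$out_dir, "pr_curve.csv"),
                     row.names = FALSE)
  }

  new_drug_result <- NULL
  if (cfg$new_drug) {
    new_drug_result <- new_drug_precision_at_1(
      fused$UDRS, fused$UDIS, inputs$Y,
      net_cfg = cfg$network, bal_cfg = cfg$balance, seed = cfg$seed)
    metrics$new_drug <- new_drug_result[c("successes", "total", "fraction")]
    logf("new-drug experiment: %d/%d held-out diseases ranked first (fraction %.4f)",
         new_drug_result$successes, new_drug_result$total,
         new_drug_result$fraction)
  }

  if (cfg$predict_unknowns) {
    nc <- cfg$network
    nc$seed <- cfg$seed
    bc <- cfg$balance
    bc$seed <- cfg$seed
    full_model <- train(build_model(ncol(table$features), nc),
                        smote(table, bc), nc)
    scores <- predict_scores(full_model, table$features)
    unknown <- table$label == 0 & table$provenance == "observed"
    cand <- data.frame(drug = table$drug[unknown],
                       disease = table$disease[unknown],
                       score = scores[unknown])
    cand <- cand[order(cand$disease, -cand$score, cand$drug), ]
    utils::write.csv(cand, file.path(cfg$out_dir, "ranked_candidates.csv"),
                     row.names = FALSE)
    logf("comprehensive prediction: scored %d unknown pairs", nrow(cand))
  }

  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(report = report, fused = fused, inputs = inputs,
                 new_drug = new_drug_result, out_dir = cfg$out_dir))
}
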