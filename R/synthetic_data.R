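# Seeded synthetic benchmark with planted group structure. Drugs and
# diseases belong to latent groups; each group has a random binary
# prototype per feature view and entity profiles are noisy copies of their
# prototype. A binary group-compatibility table drives the association
# matrix: compatible (drug group, disease group) pairs associate with
# probability p_hi, incompatible ones with p_lo. The planted affinity
# matrix (p_hi / p_lo per pair) is returned as ground truth, so ranking
# experiments have an exact oracle.

#' Synthetic benchmark parameters
#'
#' Default view widths differ per view (64/48/32 drug-side, 48/32
#' disease-side) so that shape mix-ups surface immediately.
#'
#' @param m,n drug and disease counts.
#' @param G,H drug and disease group counts (`G <= m`, `H <= n`).
#' @param drug_features integer vector of widths for the three drug views
#'   (chemical structure, side effects, targets).
#' @param disease_features widths for the two disease views (phenotype,
#'   targets).
#' @param p_hi,p_lo association probability for compatible / incompatible
#'   group pairs, `0 <= p_lo < p_hi <= 1`.
#' @param bit_noise per-bit flip probability of profile bits, in
#'   `[0, 0.5)`.
#' @param singleton_fraction fraction of drugs post-processed to exactly
#'   one association (populates the new-drug experiment cohort).
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(m = 60L, n = 40L, G = 4L, H = 4L,
                             drug_features = c(chemical_structure = 64L,
                                               side_effect = 48L,
                                               drug_target = 32L),
                             disease_features = c(phenotype = 48L,
                                                  disease_target = 32L),
                             p_hi = 0.9, p_lo = 0.02, bit_noise = 0.05,
                             singleton_fraction = 0, seed = 7L) {
  if (!(p_lo >= 0 && p_lo < p_hi && p_hi <= 1)) {
    stop_fusedda("need 0 <= p_lo < p_hi <= 1", "fusedda_config_error")
  }
  if (bit_noise < 0 || bit_noise >= 0.5) {
    stop_fusedda("bit_noise must lie in [0, 0.5)", "fusedda_config_error")
  }
  if (G > m || H > n || G < 1 || H < 1 || m < 1 || n < 1) {
    stop_fusedda("need 1 <= G <= m and 1 <= H <= n", "fusedda_config_error")
  }
  if (singleton_fraction < 0 || singleton_fraction > 1) {
    stop_fusedda("singleton_fraction must lie in [0, 1]",
                 "fusedda_config_error")
  }
  if (length(drug_features) != 3 || length(disease_features) != 2) {
    stop_fusedda("need 3 drug view widths and 2 disease view widths",
                 "fusedda_config_error")
  }
  structure(list(m = as.integer(m), n = as.integer(n),
                 G = as.integer(G), H = as.integer(H),
                 drug_features = drug_features,
                 disease_features = disease_features,
                 p_hi = p_hi, p_lo = p_lo, bit_noise = bit_noise,
                 singleton_fraction = singleton_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# one noisy-prototype profile view for `ids` assigned to `groups`
make_view <- function(ids, groups, n_groups, width, noise, view_name) {
  proto <- matrix(stats::rbinom(n_groups * width, 1, 0.5), n_groups, width)
  vals <- proto[groups, , drop = FALSE]
  flips <- matrix(stats::rbinom(length(vals), 1, noise),
                  nrow(vals), ncol(vals))
  vals <- abs(vals - flips)
  dimnames(vals) <- list(ids, paste0("f", seq_len(width)))
  feature_profile(vals, view_name)
}

#' Generate a synthetic benchmark dataset
#'
#' @param cfg a [synthetic_config()].
#' @return list with `drug_profiles` (3 `feature_profile`s),
#'   `disease_profiles` (2), `Y` (`association_matrix`), and `truth`
#'   (drug/disease group labels, compatibility table `C`, and the planted
#'   `affinity` matrix).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    drug_ids <- sprintf("dr%03d", seq_len(cfg$m))
    disease_ids <- sprintf("di%03d", seq_len(cfg$n))
    drug_groups <- rep(seq_len(cfg$G), length.out = cfg$m)      # round-robin
    disease_groups <- rep(seq_len(cfg$H), length.out = cfg$n)

    dviews <- c("chemical_structure", "side_effect", "drug_target")
    drug_profiles <- lapply(seq_along(dviews), function(v) {
      make_view(drug_ids, drug_groups, cfg$G, cfg$drug_features[v],
                cfg$bit_noise, dviews[v])
    })
    names(drug_profiles) <- dviews
    iviews <- c("phenotype", "disease_target")
    disease_profiles <- lapply(seq_along(iviews), function(v) {
      make_view(disease_ids, disease_groups, cfg$H, cfg$disease_features[v],
                cfg$bit_noise, iviews[v])
    })
    names(disease_profiles) <- iviews

    # compatibility table; resampled until both outcomes occur, otherwise
    # Y would be single-class and untrainable
    repeat {
      C <- matrix(stats::rbinom(cfg$G * cfg$H, 1, 0.5), cfg$G, cfg$H)
      if (any(C == 1) && any(C == 0)) break
    }

    affinity <- matrix(ifelse(C[drug_groups, disease_groups] == 1,
                              cfg$p_hi, cfg$p_lo),
                       cfg$m, cfg$n, dimnames = list(drug_ids, disease_ids))
    Y <- matrix(stats::rbinom(cfg$m * cfg$n, 1, affinity), cfg$m, cfg$n,
                dimnames = list(drug_ids, disease_ids))

    n_single <- round(cfg$singleton_fraction * cfg$m)
    if (n_single > 0) {
      chosen <- sample.int(cfg$m, n_single)
      for (d in chosen) {
        best <- which.max(affinity[d, ])       # ties: smallest index
        Y[d, ] <- 0
        Y[d, best] <- 1
      }
    }

    list(drug_profiles = drug_profiles,
         disease_profiles = disease_profiles,
         Y = suppressWarnings(association_matrix(Y)),
         truth = list(drug_groups = stats::setNames(drug_groups, drug_ids),
                      disease_groups = stats::setNames(disease_groups,
                                                       disease_ids),
                      C = C, affinity = affinity))
  })
}

#' Permute association labels (negative control)
#'
#' Shuffles all `m * n` entries of the association matrix uniformly,
#' preserving the number of ones; used as a leakage control — a pipeline
#' evaluated on permuted labels must score at chance.
#'
#' @param Y an `association_matrix`.
#' @param seed integer seed.
#' @return the permuted `association_matrix`.
#' @export
permute_labels <- function(Y, seed = 1L) {
  stopifnot(inherits(Y, "association_matrix"))
  vals <- as.numeric(Y)
  perm <- withr::with_seed(seed, sample(vals))
  Y2 <- matrix(perm, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  suppressWarnings(association_matrix(Y2))
}

#' Write a synthetic dataset to CSV files
#'
#' Emits the five profile files, the association matrix, the planted
#' affinity matrix and the group labels under `dir` in the package's
#' standard CSV dialect.
#'
#' @param data output of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wp <- function(p, file) {
    df <- data.frame(id = rownames(p$values), p$values, check.names = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  for (nm in names(data$drug_profiles)) {
    wp(data$drug_profiles[[nm]], paste0("drug_", nm, ".csv"))
  }
  for (nm in names(data$disease_profiles)) {
    wp(data$disease_profiles[[nm]], paste0("disease_", nm, ".csv"))
  }
  Ydf <- data.frame(id = rownames(data$Y), unclass(data$Y),
                    check.names = FALSE)
  utils::write.csv(Ydf, file.path(dir, "associations.csv"),
                   row.names = FALSE, quote = FALSE)
  Adf <- data.frame(id = rownames(data$truth$affinity),
                    data$truth$affinity, check.names = FALSE)
  utils::write.csv(Adf, file.path(dir, "truth_affinity.csv"),
                   row.names = FALSE, quote = FALSE)
  gdf <- data.frame(id = c(names(data$truth$drug_groups),
                           names(data$truth$disease_groups)),
                    class = c(rep("drug", length(data$truth$drug_groups)),
                              rep("disease", length(data$truth$disease_groups))),
                    group = c(data$truth$drug_groups,
                              data$truth$disease_groups))
  utils::write.csv(gdf, file.path(dir, "truth_groups.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
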