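test_that("generation is fully deterministic per seed", {
  cfg <- synthetic_config(m = 25, n = 18, seed = 7)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a, b)
  c <- generate_synthetic(synthetic_config(m = 25, n = 18, seed = 8))
  expect_false(identical(a$Y, c$Y))
})

test_that("zero noise makes within-group profiles identical in every view", {
  data <- generate_synthetic(synthetic_config(m = 12, n = 8, G = 3, H = 2,
                                              bit_noise = 0, seed = 2))
  for (p in c(data$drug_profiles, data$disease_profiles)) {
    S <- profile_to_similarity(p)$S
    groups <- if (nrow(p$values) == 12) data$truth$drug_groups else data$truth$disease_groups
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) > 1) {
        expect_equal(unname(S[idx, idx]),
                     matrix(1, length(idx), length(idx)))
      }
    }
  }
})

test_that("deterministic limit p_hi=1, p_lo=0 gives the exact block pattern", {
  cfg <- synthetic_config(m = 16, n = 12, G = 4, H = 3, p_hi = 1,
                          p_lo = 1e-12, seed = 5)
  # p_lo must be < p_hi and the config requires p_lo >= 0; use 0 directly
  cfg$p_lo <- 0
  data <- generate_synthetic(cfg)
  tg <- data$truth
  want <- tg$C[tg$drug_groups, tg$disease_groups]
  expect_identical(unname(unclass(data$Y)), unname(want * 1))
})

test_that("association density is within 3 binomial SE of its expectation", {
  withr::with_seed(70, {
    for (s in sample(1e6, 3)) {
      cfg <- synthetic_config(m = 60, n = 40, seed = s)
      data <- generate_synthetic(cfg)
      p_cell <- mean(ifelse(
        data$truth$C[data$truth$drug_groups, data$truth$disease_groups] == 1,
        cfg$p_hi, cfg$p_lo))
      n_cell <- cfg$m * cfg$n
      se <- sqrt(p_cell * (1 - p_cell) / n_cell)
      expect_lt(abs(mean(data$Y) - p_cell), 3 * se)
    }
  })
})

test_that("within-group cosine exceeds between-group by a clear margin", {
  margins <- vapply(1:5, function(s) {
    data <- generate_synthetic(synthetic_config(m = 30, n = 20,
                                                bit_noise = 0.05, seed = s))
    S <- profile_to_similarity(data$drug_profiles$chemical_structure)$S
    g <- data$truth$drug_groups
    same <- outer(g, g, `==`) & !diag(length(g))
    mean(S[same]) - mean(S[!same & !diag(length(g))])
  }, 0)
  expect_true(all(margins > 0.2))
})

test_that("singleton post-processing yields the new-drug cohort", {
  cfg <- synthetic_config(m = 20, n = 10, singleton_fraction = 0.3, seed = 4)
  data <- generate_synthetic(cfg)
  expect_gte(sum(rowSums(data$Y) == 1), round(0.3 * 20))
})

test_that("permute_labels preserves the count of ones and is seeded", {
  data <- generate_synthetic(synthetic_config(m = 10, n = 8, seed = 3))
  P1 <- permute_labels(data$Y, seed = 5)
  expect_equal(sum(P1), sum(data$Y))
  expect_identical(dim(P1), dim(data$Y))
  expect_identical(unclass(permute_labels(data$Y, seed = 5)), unclass(P1))

  zero <- suppressWarnings(association_matrix(
    matrix(0, 3, 3, dimnames = list(paste0("d", 1:3), paste0("i", 1:3)))))
  expect_identical(unclass(suppressWarnings(permute_labels(zero, 1))),
                   unclass(zero))
})

test_that("a lone association lands uniformly over cells under permutation", {
  Y <- suppressWarnings(association_matrix(
    matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))))
  counts <- integer(4)
  for (s in seq_len(10000)) {
    P <- suppressWarnings(permute_labels(Y, seed = s))
    counts[which(P == 1)] <- counts[which(P == 1)] + 1
  }
  p <- 1 / 4
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(counts / 10000 - p) < 3.5 * se))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(p_hi = 0.3, p_lo = 0.5), "p_lo < p_hi")
  expect_error(synthetic_config(bit_noise = 0.5), "bit_noise")
  expect_error(synthetic_config(m = 3, G = 5), "G <= m")
  expect_error(synthetic_config(singleton_fraction = 1.2), "singleton")
})

test_that("written synthetic datasets read back through core_data", {
  data <- generate_synthetic(synthetic_config(m = 8, n = 6, seed = 9))
  dir <- withr::local_tempdir()
  write_synthetic(data, dir)
  p <- read_binary_profile(file.path(dir, "drug_chemical_structure.csv"),
                           "chemical_structure")
  expect_identical(p$values, data$drug_profiles$chemical_structure$values)
  Y <- read_association_matrix(file.path(dir, "associations.csv"))
  expect_identical(unclass(Y), unclass(data$Y))
})
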