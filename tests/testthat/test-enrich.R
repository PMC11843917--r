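test_that("crude protein is nitrogen times 6.25", {
  expect_equal(crude_protein_pct(1.792), 11.2)
  expect_equal(crude_protein_pct(0), 0)
  expect_equal(crude_protein_pct(2.0), 12.5)
  expect_error(crude_protein_pct(-1), ">= 0")
})

test_that("mass balance conserves when outputs equal the input", {
  m <- tibble::tibble(fraction = c("grass", "pulp", "juice"),
                      mass_g = c(100, 60, 40),
                      dm_pct = c(20, 20, 20),
                      cp_pct = c(12, 12, 12))
  bal <- mass_balance(m)
  expect_equal(bal$mass_loss_g, 0)
  expect_equal(bal$dm_loss_pct, 0)
  expect_equal(bal$cp_loss_pct, 0)
  out <- bal$fractions[bal$fractions$fraction != "grass", ]
  expect_equal(sum(out$dm_distribution_pct), 100)
  expect_equal(sum(out$cp_distribution_pct), 100)
  # distributions are invariant to the unit of mass
  m2 <- dplyr::mutate(m, mass_g = mass_g * 1000)
  expect_equal(mass_balance(m2)$fractions$dm_distribution_pct,
               bal$fractions$dm_distribution_pct)
  expect_error(mass_balance(m[1:2, ]), "juice")
})

test_that("replicate-presence filter builds sets and Venn counts", {
  samples <- c(paste0("g_", 1:3), paste0("j_", 1:3))
  m <- matrix(1, 4, 6, dimnames = list(paste0("p", 1:4), samples))
  m["p1", c("j_1", "j_2")] <- 1; m["p1", "j_3"] <- NA   # 2 of 3 juice
  m["p2", c("j_2", "j_3")] <- NA                         # 1 of 3 juice
  m["p2", c("g_2", "g_3")] <- NA                         # 1 of 3 grass
  m["p3", paste0("g_", 1:3)] <- NA                       # juice only
  sets <- replicate_presence_filter(
    m, list(grass = paste0("g_", 1:3), juice = paste0("j_", 1:3)))
  expect_true("p1" %in% sets$sets$juice)
  expect_false("p2" %in% sets$sets$juice)
  expect_false("p2" %in% sets$sets$grass)
  expect_setequal(sets$sets$grass, c("p1", "p4"))
  expect_setequal(sets$sets$juice, c("p1", "p3", "p4"))
  expect_equal(
    sets$intersections$n[sets$intersections$combination == "grass&juice"], 2)
})

test_that("log-LFQ normalization is scale-invariant and centers medians", {
  set.seed(11)
  m <- matrix(rlnorm(60, 10, 1), 20, 3,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:3)))
  n1 <- normalize_log_lfq(m)
  n2 <- normalize_log_lfq(m * 8)
  expect_equal(n1, n2)
  # scaling a single sample is also absorbed
  m3 <- m; m3[, 2] <- m3[, 2] * 8
  expect_equal(normalize_log_lfq(m3), n1)
  const <- matrix(4, 5, 2, dimnames = list(paste0("p", 1:5), c("a", "b")))
  expect_true(all(normalize_log_lfq(const) == 0))
  bad <- m; bad[1, 1] <- 0
  expect_error(normalize_log_lfq(bad), "positive")
})

test_that("NMAR imputation draws from the downshifted normal", {
  set.seed(12)
  obs <- rnorm(2000, 20, 2)
  col <- c(obs, rep(NA_real_, 10000))
  m <- matrix(col, ncol = 1, dimnames = list(NULL, "s1"))
  imp <- impute_nmar(m, seed = 13)
  drawn <- imp$mat[imp$mask]
  mu <- mean(obs); sg <- sd(obs)
  expect_equal(mean(drawn), mu - 1.8 * sg, tolerance = 0.02)
  expect_equal(sd(drawn), 0.3 * sg, tolerance = 0.02)
  # observed cells bit-identical; deterministic under the seed
  expect_identical(imp$mat[!imp$mask], m[!imp$mask])
  expect_identical(impute_nmar(m, seed = 13)$mat, imp$mat)
  # no missing values: unchanged, empty mask
  full <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  imp2 <- impute_nmar(full, seed = 1)
  expect_identical(imp2$mat, full)
  expect_false(any(imp2$mask))
  expect_error(impute_nmar(matrix(c(1, NA, NA), 3, 1,
                                  dimnames = list(NULL, "only1"))),
               "only1")
})

test_that("differential calls require both FDR and fold-change gates", {
  set.seed(14)
  base <- matrix(rnorm(50 * 6, 20, 0.1), 50, 6,
                 dimnames = list(paste0("p", 1:50),
                                 c(paste0("a", 1:3), paste0("b", 1:3))))
  same <- pairwise_differential(base, paste0("a", 1:3), paste0("b", 1:3))
  expect_false(any(same$differential))

  # strong significance but |log2FC| = 0.9: blocked by the fold gate
  gated <- base
  gated["p1", paste0("a", 1:3)] <- c(20.9, 20.9, 20.9) + rnorm(3, 0, 1e-4)
  gated["p1", paste0("b", 1:3)] <- c(20, 20, 20) + rnorm(3, 0, 1e-4)
  gated["p1", paste0("a", 1:3)] <-
    gated["p1", paste0("b", 1:3)] + 0.9 + rnorm(3, 0, 1e-4)
  res <- pairwise_differential(gated, paste0("a", 1:3), paste0("b", 1:3))
  p1 <- res[res$protein == "p1", ]
  expect_lt(p1$adj_p_value, 0.05)
  expect_false(p1$differential)

  # zero variance in both groups: degenerate flag, usable p
  deg <- base
  deg["p2", ] <- c(5, 5, 5, 3, 3, 3)
  res2 <- pairwise_differential(deg, paste0("a", 1:3), paste0("b", 1:3))
  p2 <- res2[res2$protein == "p2", ]
  expect_true(p2$degenerate)
  expect_false(is.na(p2$p_value))
})

test_that("group riBAQ statistics separate a strongly shifted fraction", {
  groups <- list(grass = paste0("g", 1:3), pulp = paste0("pu", 1:3),
                 juice = paste0("j", 1:3))
  samples <- unlist(groups)
  set.seed(15)
  rb <- matrix(abs(rnorm(2 * 9, 0.01, 0.0005)), 2, 9,
               dimnames = list(c("m1", "m2"), samples))
  # identical distributions: omnibus not significant
  eq <- group_abundance_stats(rb, list(fam = c("m1", "m2")), groups,
                              cumulative = FALSE)
  expect_gt(eq$omnibus$p_value, 0.05)

  # shift juice by ~10 sigma
  rb2 <- rb
  rb2[, groups$juice] <- rb2[, groups$juice] + 0.01
  sh <- group_abundance_stats(rb2, list(fam = c("m1", "m2")), groups,
                              cumulative = FALSE)
  expect_lt(sh$omnibus$p_value, 0.01)
  pw <- sh$pairwise[sh$pairwise$family == "fam", ]
  juice_contrast <- grepl("juice", pw$contrast)
  expect_true(all(pw$p_adj[juice_contrast] < 0.05))
  expect_true(all(pw$p_adj[!juice_contrast] > 0.05))

  # invariant to isoform splits that conserve the summed riBAQ
  split_rb <- rbind(rb2, m1b = rb2["m1", ] / 2)
  split_rb["m1", ] <- split_rb["m1", ] / 2
  sp <- group_abundance_stats(split_rb,
                              list(fam = c("m1", "m1b", "m2")), groups,
                              cumulative = FALSE)
  expect_equal(sp$omnibus$p_value, sh$omnibus$p_value)
})

test_that("Z-score clustering recovers constructed patterns", {
  set.seed(16)
  pattern <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0),
                   c(0, 1, 0, 1))
  mat <- pattern[rep(1:4, each = 5), ] + matrix(rnorm(80, 0, 0.05), 20, 4)
  rownames(mat) <- paste0("r", 1:20)
  cl <- zscore_cluster(mat, distance_cutoff = 2)
  expect_equal(length(unique(cl$clusters)), 4)
  truth <- rep(1:4, each = 5)
  expect_equal(length(unique(paste(truth, cl$clusters))), 4)
  # z rows have mean 0, sd 1
  expect_equal(unname(rowMeans(cl$z)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(cl$z, 1, sd)), rep(1, 20), tolerance = 1e-12)
  # identical rows cluster together; constant rows warn
  two <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  cl2 <- zscore_cluster(two, distance_cutoff = 0.5)
  expect_identical(cl2$clusters[["a"]], cl2$clusters[["b"]])
  expect_warning(zscore_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
})
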