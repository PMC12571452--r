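test_that("fold plans partition the positives into near-equal disjoint folds", {
  ds <- random_dataset(60, 25, density = 0.3, seed = 1)
  n_pos <- sum(ds$A)
  for (seed in 1:3) {
    plan <- make_folds(ds, k = 10, seed = seed)
    sizes <- vapply(plan$folds, nrow, integer(1))
    expect_equal(sum(sizes), n_pos)
    expect_lte(max(sizes) - min(sizes), 1)
    keys <- unlist(lapply(plan$folds, function(f) paste(f[, 1], f[, 2])))
    expect_equal(length(keys), length(unique(keys)))
    expect_true(all(ds$A[do.call(rbind, plan$folds)] == 1L))
  }
  # 911 positives at k = 10: nine folds of 91, one of 92
  sizes_911 <- rep(911 %/% 10, 10) + c(1, rep(0, 9))
  expect_equal(sort(sizes_911), c(rep(91, 9), 92))

  # exactly k positives -> singleton folds
  ds_small <- association_dataset(data.frame(
    s = sprintf("s%d", 1:10), d = rep(sprintf("d%d", 1:2), 5)))
  plan_s <- make_folds(ds_small, k = 10, seed = 1)
  expect_true(all(vapply(plan_s$folds, nrow, integer(1)) == 1))

  expect_identical(make_folds(ds, 10, seed = 5), make_folds(ds, 10, seed = 5))
  expect_error(make_folds(ds, k = 1), ">= 2")
})

test_that("negative sampling stays inside the unknown-pair pool", {
  ds <- random_dataset(10, 6, density = 0.2, seed = 2)
  neg <- sample_negatives(ds, 12, seed = 3)
  expect_equal(nrow(neg), 12)
  expect_true(all(ds$A[neg] == 0L))
  expect_equal(nrow(unique(as.data.frame(neg))), 12)

  # exclusion is honored
  pool <- which(ds$A == 0L, arr.ind = TRUE)
  excl <- pool[1:5, , drop = FALSE]
  neg2 <- sample_negatives(ds, nrow(pool) - 5, exclude = excl, seed = 4)
  expect_false(any(paste(neg2[, 1], neg2[, 2]) %in%
                     paste(excl[, 1], excl[, 2])))

  # fully positive 1x1 dataset has an empty pool
  ds1 <- association_dataset(data.frame(s = "s1", d = "d1"))
  expect_error(sample_negatives(ds1, 1), "exhausted")
  # n = pool size returns the whole pool
  ds_all <- sample_negatives(ds, nrow(pool), seed = 1)
  expect_equal(nrow(ds_all), nrow(pool))
})

test_that("metrics match the worked confusion table and brute-force AUC", {
  row <- compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(row$auc, 0.75)
  expect_equal(row$acc, 0.5)
  expect_equal(row$rec, 0.5)
  expect_equal(row$spe, 0.5)
  expect_equal(row$pre, 0.5)
  expect_equal(row$f1, 0.5)

  perfect <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)

  # AUC equals concordant-pair counting on random score sets, ties included
  set.seed(5)
  for (rep in 1:6) {
    n <- sample(20:150, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(compute_metrics(scores, labels)$auc,
                 brute_force_auc(scores, labels))
  }
  expect_error(compute_metrics(c(0.1, 0.9), c(1, 1)), "single class")
})

test_that("AUPR is bounded below by prevalence for a non-degenerate scorer", {
  set.seed(6)
  for (rep in 1:5) {
    labels <- rep(c(1, 0), each = 40)
    scores <- runif(80) + 0.2 * labels
    row <- compute_metrics(scores, labels)
    expect_gte(row$aupr, 0.5 - 0.05)  # prevalence on the balanced set
  }
})

test_that("cross-validation reports 10 folds plus mean and sd, all in [0, 1]", {
  gen <- generate_planted_bipartite(synthetic_config(n_s = 50, n_d = 12,
                                                     density = 0.12,
                                                     seed = 3))
  feats <- list(snorna = gen$snorna_features, disease = gen$disease_features)
  cfg <- model_config(epochs = 15, seed = 3)
  rep10 <- cross_validate(gen$dataset, feats, cfg, k = 10, seed = 3)
  expect_equal(nrow(rep10), 12)
  expect_equal(rep10$fold, c(as.character(1:10), "mean", "sd"))
  expect_equal(colnames(rep10),
               c("fold", "auc", "aupr", "f1", "acc", "rec", "spe", "pre"))
  vals <- as.matrix(rep10[1:11, -1])
  expect_true(all(vals >= 0 & vals <= 1))
  means <- colMeans(as.matrix(rep10[1:10, -1]))
  expect_equal(unname(means), unname(unlist(rep10[11, -1])))
})

test_that("case-study ranking obeys the masking and exclusion contracts", {
  gen <- generate_planted_bipartite(synthetic_config(n_s = 40, n_d = 10,
                                                     density = 0.12,
                                                     seed = 6))
  feats <- list(snorna = gen$snorna_features, disease = gen$disease_features)
  cfg <- model_config(epochs = 15, seed = 6)
  target <- gen$dataset$disease_ids[which.max(colSums(gen$dataset$A))]

  ranked <- rank_candidates(gen$dataset, feats, cfg, target,
                            mode = "novel-disease", top_n = 15)
  expect_lte(nrow(ranked), 15)
  expect_true(all(diff(ranked$score) <= 0))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))

  ranked2 <- rank_candidates(gen$dataset, feats, cfg, target,
                             mode = "novel-association", top_n = 15)
  j <- match(target, gen$dataset$disease_ids)
  known <- gen$dataset$snorna_ids[gen$dataset$A[, j] == 1L]
  expect_false(any(ranked2$snorna_id %in% known))
  expect_true(all(diff(ranked2$score) <= 0))

  expect_error(rank_candidates(gen$dataset, feats, cfg, "bogus",
                               mode = "novel-disease"), "unknown disease")
})
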