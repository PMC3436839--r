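make_positives <- function(drugs, targets, pairs) {
  interaction_dataset(drugs[pairs[, 1]], targets[pairs[, 2]])
}

test_that("negative sampling complements the positive set exactly", {
  drugs <- paste0("d", 1:3)
  targets <- paste0("t", 1:3)
  pos <- make_positives(drugs, targets, rbind(c(1, 1), c(2, 3)))
  all_neg <- sample_negatives(pos, negative_sampling_config("ALL"),
                              compound_ids = drugs, protein_ids = targets)
  expect_equal(nrow(all_neg), 7L)  # 9 pairs minus 2 positives
  expect_true(all(all_neg$label == -1))
  key <- function(d) paste(d$compound_id, d$protein_id)
  expect_length(intersect(key(all_neg), key(pos)), 0L)

  # ratio 1: as many negatives as positives, disjoint
  withr::with_seed(61, {
    big <- interaction_dataset(paste0("d", sample(1:20, 10, TRUE)),
                               paste0("t", 1:10))
  })
  neg1 <- sample_negatives(big, negative_sampling_config(1, seed = 5))
  expect_equal(nrow(neg1), 10L)
  expect_length(intersect(key(neg1), key(big)), 0L)

  # ratio capped at the pool size
  capped <- sample_negatives(pos, negative_sampling_config(100, seed = 5),
                             compound_ids = drugs, protein_ids = targets)
  expect_equal(nrow(capped), 7L)

  # reproducibility and seed-independence of ALL
  n1 <- sample_negatives(big, negative_sampling_config(2, seed = 9))
  n2 <- sample_negatives(big, negative_sampling_config(2, seed = 9))
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  a1 <- sample_negatives(pos, negative_sampling_config("ALL", seed = 1),
                         compound_ids = drugs, protein_ids = targets)
  a2 <- sample_negatives(pos, negative_sampling_config("ALL", seed = 999),
                         compound_ids = drugs, protein_ids = targets)
  expect_identical(as.data.frame(a1), as.data.frame(a2))

  # saturated grid has no candidates
  sat <- make_positives("d1", "t1", cbind(1, 1))
  expect_error(sample_negatives(sat, negative_sampling_config(1)), "no candidate")
})

test_that("pairwise folds are balanced, partition the pairs, and are reproducible", {
  withr::with_seed(67, {
    data <- interaction_dataset(paste0("d", 1:10), paste0("t", sample(1:10)))
  })
  plan <- cv_plan("pairwise", k = 5, seed = 3)
  folds <- pairwise_cv_split(data, plan)
  sizes <- vapply(folds, function(f) length(f$test), numeric(1))
  expect_true(all(sizes == 2))
  expect_setequal(unlist(lapply(folds, `[[`, "test")), 1:10)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), 1:10)
  }
  # disjoint test sets across folds
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(anyDuplicated(tests), 0L)
  expect_identical(folds, pairwise_cv_split(data, plan))
  expect_error(pairwise_cv_split(data, cv_plan("pairwise", k = 11)), "at least")
})

test_that("blockwise folds satisfy the cold-start contract", {
  # 5 drugs x 5 targets, fully labeled grid: each test block is 1 x 1
  grid <- expand.grid(d = paste0("d", 1:5), t = paste0("t", 1:5))
  data <- interaction_dataset(grid$d, grid$t,
                              rep(c(1, -1), length.out = 25))
  folds <- blockwise_cv_split(data, cv_plan("blockwise", k = 5, seed = 7))
  for (f in folds) {
    expect_equal(length(f$test), 1L)
    td <- unique(data$compound_id[f$test])
    tt <- unique(data$protein_id[f$test])
    expect_length(intersect(td, data$compound_id[f$train]), 0L)
    expect_length(intersect(tt, data$protein_id[f$train]), 0L)
  }

  # random sparse labeled set: enumerate the contract across folds
  withr::with_seed(71, {
    pool2 <- expand.grid(d = paste0("d", 1:12), t = paste0("t", 1:10))
    rows2 <- sample(nrow(pool2), 30)
    d2 <- interaction_dataset(pool2$d[rows2], pool2$t[rows2])
  })
  folds2 <- blockwise_cv_split(d2, cv_plan("blockwise", k = 4, seed = 11))
  for (f in folds2) {
    expect_length(intersect(unique(d2$compound_id[f$test]),
                            unique(d2$compound_id[f$train])), 0L)
    expect_length(intersect(unique(d2$protein_id[f$test]),
                            unique(d2$protein_id[f$train])), 0L)
    # no pair in both train and test
    expect_length(intersect(f$train, f$test), 0L)
  }
})

test_that("AUC equals brute-force pair counting and its invariances", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, -1, -1)), 1.0)
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both")

  withr::with_seed(73, {
    for (rep in 1:10) {
      n <- 50
      s <- sample(round(rnorm(n), 1))  # rounded scores force ties
      y <- sample(c(-1, 1), n, TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
      a <- roc_auc(s, y)
      expect_equal(a, auc_bruteforce(s, y))
      # invariance under strictly increasing transform
      expect_equal(roc_auc(exp(s / 2), y), a)
      # negated scores mirror the AUC
      expect_equal(roc_auc(-s, y) + a, 1)
      expect_gte(a, 0); expect_lte(a, 1)
    }
  })
})

test_that("hyper-parameter selection maximizes inner AUC with ties to small C", {
  d <- toy_design(seed = 79, n = 60, D = 8, Dp = 5)
  plan <- cv_plan("pairwise", k = 3, seed = 5)
  single <- select_hyperparameter(d, "L1LOG", 0.5, plan)
  expect_equal(single$C, 0.5)

  # a separable toy: high C reaches AUC 1, tiny C scores constant 0 (AUC .5)
  n <- 24
  X <- matrix(0, n, 4)
  y <- rep(c(1, -1), each = n / 2)
  X[y > 0, 1] <- 1
  X[y < 0, 2] <- 1
  sep <- design_from_matrix(X, y)
  sep$pairs <- data.frame(row = 1:n)
  sel <- select_hyperparameter(sep, "L1LOG", c(1e-4, 10), plan)
  expect_equal(sel$C, 10)
  expect_equal(max(sel$table$mean_auc), 1.0)

  # exact tie on a two-point grid goes to the smaller C
  flat <- design_from_matrix(matrix(0, 12, 3), rep(c(1, -1), 6))
  flat$pairs <- data.frame(row = 1:12)
  tie <- select_hyperparameter(flat, "L1LOG", c(0.1, 1), plan)
  expect_equal(tie$C, 0.1)
})

test_that("the experiment grid is complete, reproducible, and seed-derived", {
  cfg <- generator_config(n_drugs = 30, n_targets = 25, D = 15, D_prime = 12,
                          p_sub = 0.15, p_dom = 0.15, K_true = 4,
                          bias = qlogis(0.05), seed = 83)
  ds <- generate_dataset(cfg)
  plan <- cv_plan("pairwise", k = 3, repeats = 2, seed = 19)
  res <- run_experiment(ds$positives, ds$compounds, ds$proteins,
                        models = c("L1LOG", "L2LOG"), ratios = c(1, 5),
                        plan = plan)
  expect_s3_class(res, "evaluation_result")
  expect_equal(nrow(res), 4L)  # |models| x |ratios|
  expect_true(all(res$mean_auc >= 0 & res$mean_auc <= 1))
  expect_true(all(c("mode", "model", "ratio", "mean_auc", "sd_auc",
                    "n_features_positive") %in% names(res)))
  details <- attr(res, "details")
  expect_equal(sort(unique(details$repeat_)), 1:2)

  res2 <- run_experiment(ds$positives, ds$compounds, ds$proteins,
                         models = c("L1LOG", "L2LOG"), ratios = c(1, 5),
                         plan = plan)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})
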