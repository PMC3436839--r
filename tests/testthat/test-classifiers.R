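test_that("objective at the zero vector has its closed form", {
  d <- toy_design(seed = 3, n = 17)
  w0 <- make_weights(numeric(0), numeric(0))
  C <- 0.7
  expect_equal(objective_value(w0, d, training_config("L1LOG", C = C)),
               C * 17 * log(2))
  expect_equal(objective_value(w0, d, training_config("L1SVM", C = C)),
               C * 17)
})

test_that("objective agrees with a dense loop recomputation for all models", {
  withr::with_seed(5, {
    for (rep in 1:8) {
      n <- 20
      p <- 12
      X <- matrix(rbinom(n * p, 1, 0.3), n, p)
      y <- sample(c(-1, 1), n, TRUE)
      d <- design_from_matrix(X, y)
      idx <- sort(sample(0:(p - 1), 5))
      wv <- rnorm(5)
      b <- rnorm(1)
      w <- make_weights(idx, wv, intercept = b)
      wd <- numeric(p); wd[idx + 1] <- wv
      for (m in c("L1LOG", "L1SVM", "L2LOG", "L2SVM")) {
        C <- runif(1, 0.1, 3)
        expect_equal(
          objective_value(w, d, training_config(m, C = C)),
          objective_bruteforce(wd, b, X, y, m, C),
          tolerance = 1e-10
        )
      }
    }
  })
})

test_that("vanishing C drives L1 weights to zero", {
  d <- toy_design(seed = 8)
  for (m in c("L1LOG", "L1SVM")) {
    w <- train_classifier(d, training_config(m, C = 1e-6))
    expect_length(w$weight, 0)
  }
})

test_that("a perfectly separating pair feature gets the largest positive weight", {
  # feature 4 is active in exactly the positives
  n <- 30
  withr::with_seed(2, {
    X <- matrix(rbinom(n * 8, 1, 0.3), n, 8)
    y <- rep(c(1, -1), length.out = n)
    X[, 5] <- as.numeric(y > 0)
  })
  d <- design_from_matrix(X, y)
  for (m in c("L1LOG", "L1SVM")) {
    w <- train_classifier(d, training_config(m, C = 2))
    top <- w$index[which.max(w$weight)]
    expect_equal(top, 4)
    expect_gt(max(w$weight), 0)
  }
})

test_that("training is deterministic and beats the zero vector", {
  d <- toy_design(seed = 13, n = 60)
  for (m in c("L1LOG", "L1SVM", "L2LOG", "L2SVM")) {
    cfg <- training_config(m, C = 1)
    w1 <- train_classifier(d, cfg)
    w2 <- train_classifier(d, cfg)
    expect_identical(w1$weight, w2$weight)
    expect_identical(w1$index, w2$index)
    expect_lte(objective_value(w1, d, cfg),
               objective_value(make_weights(numeric(0), numeric(0)), d, cfg))
  }
})

test_that("logistic fits reach the reference optimum on small instances", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 40; p <- 6
      X <- matrix(rbinom(n * p, 1, 0.35), n, p)
      y <- sample(c(-1, 1), n, TRUE)
      K <- diag(y) %*% X
      d <- design_from_matrix(X, y)
      C <- runif(1, 0.3, 3)
      for (m in c("L1LOG", "L2LOG")) {
        cfg <- training_config(m, C = C, tolerance = 1e-6)
        w <- train_classifier(d, cfg)
        ref <- logreg_min_lbfgs(K, C, if (m == "L1LOG") "l1" else "l2")
        expect_lte(objective_value(w, d, cfg), ref + 1e-4 * (1 + abs(ref)))
      }
    }
  })
})

test_that("hinge fits reach the reference optimum on small instances", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 15; p <- 3
      X <- matrix(rbinom(n * p, 1, 0.5), n, p)
      y <- sample(c(-1, 1), n, TRUE)
      K <- diag(y) %*% X
      d <- design_from_matrix(X, y)
      C <- runif(1, 0.2, 2)
      cfg <- training_config("L1SVM", C = C, tolerance = 1e-7,
                             max_iterations = 50000L)
      w <- train_classifier(d, cfg)
      ref <- l1svm_min_enum(K, C)
      expect_equal(objective_value(w, d, cfg), ref,
                   tolerance = 1e-5)
    }
    for (rep in 1:5) {
      n <- 25; p <- 6
      X <- matrix(rbinom(n * p, 1, 0.4), n, p)
      y <- sample(c(-1, 1), n, TRUE)
      K <- diag(y) %*% X
      d <- design_from_matrix(X, y)
      C <- runif(1, 0.2, 2)
      cfg <- training_config("L2SVM", C = C, tolerance = 1e-7,
                             max_iterations = 50000L)
      w <- train_classifier(d, cfg)
      ref <- l2svm_min_dual(K, C)
      expect_lte(objective_value(w, d, cfg), ref + 1e-4 * (1 + abs(ref)))
    }
  })
})

test_that("L1 sparsity is non-increasing as C decreases on a grid", {
  d <- toy_design(seed = 17, n = 80, D = 8, Dp = 6)
  for (m in c("L1LOG", "L1SVM")) {
    nnz <- vapply(c(10, 1, 0.3, 0.1, 0.03), function(C) {
      length(train_classifier(d, training_config(m, C = C))$weight)
    }, numeric(1))
    expect_true(all(diff(nnz) <= 0))
  }
})

test_that("prediction scores are the sparse dot product plus intercept", {
  sp <- descriptor_space(sprintf("SUB%d", c(158, 200)), c("PF00106", "PF99999"))
  # a single weight 2.1468 on the (SUB158, PF00106) pair feature
  k <- pair_index(0, 0, sp)
  w <- make_weights(k, 2.1468)
  x <- tensor_featurize(compound_fingerprint("d", 0L, 2),
                        protein_fingerprint("t", 0L, 2), sp)
  expect_equal(predict_score(w, x), 2.1468)
  expect_equal(predict_score(make_weights(numeric(0), numeric(0)), x), 0)

  withr::with_seed(23, {
    for (rep in 1:10) {
      fp <- random_fingerprints()
      v <- tensor_featurize(fp$c, fp$p, fp$space)
      dim_total <- fp$space$D * fp$space$D_prime
      idx <- sort(sample(0:(dim_total - 1), 15))
      wv <- rnorm(15)
      wr <- make_weights(idx, wv, intercept = 0.3)
      dense_w <- numeric(dim_total); dense_w[idx + 1] <- wv
      dense_x <- numeric(dim_total); dense_x[as.numeric(v) + 1] <- 1
      expect_equal(predict_score(wr, v), sum(dense_w * dense_x) + 0.3)
    }
  })
})

test_that("the pairwise kernel factorizes the tensor inner product", {
  fp <- random_fingerprints(8, 9, 4, 3)
  expect_equal(pairwise_kernel(fp$c, fp$p, fp$c, fp$p),
               length(fp$c$active) * length(fp$p$active))
  c2 <- compound_fingerprint("c2", setdiff(0:7, fp$c$active), 8)
  expect_equal(pairwise_kernel(fp$c, fp$p, c2, fp$p), 0)

  withr::with_seed(29, {
    for (rep in 1:20) {
      D <- sample(4:9, 1); Dp <- sample(4:9, 1)
      sp <- descriptor_space(sprintf("S%d", 1:D), sprintf("P%d", 1:Dp))
      mk <- function(n, m) sort(sample(0:(n - 1), sample(0:m, 1)))
      c1 <- compound_fingerprint("a", mk(D, D), D)
      c2 <- compound_fingerprint("b", mk(D, D), D)
      p1 <- protein_fingerprint("u", mk(Dp, Dp), Dp)
      p2 <- protein_fingerprint("v", mk(Dp, Dp), Dp)
      v1 <- tensor_featurize(c1, p1, sp)
      v2 <- tensor_featurize(c2, p2, sp)
      expect_equal(pairwise_kernel(c1, p1, c2, p2),
                   length(intersect(as.numeric(v1), as.numeric(v2))))
    }
  })
  expect_error(
    pairwise_kernel(fp$c, fp$p, compound_fingerprint("z", 0L, 5), fp$p),
    "different spaces"
  )
})

test_that("single-class data and unknown models are rejected", {
  X <- matrix(rbinom(40, 1, 0.5), 10, 4)
  d <- design_from_matrix(X, rep(1, 10))
  expect_error(train_classifier(d, training_config("L1LOG")), "both classes")
  expect_error(training_config("RIDGE"), "arg")
  expect_error(training_config("L1LOG", C = -1), "positive")
})
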