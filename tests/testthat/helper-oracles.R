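# Independent brute-force oracles used across the suite. These deliberately
# take the slow, dense, obviously-correct route and share no code with the
# package internals they check.

# dense double-loop tensor product: all D x D' entries
dense_tensor_active <- function(c_active, p_active, D, Dp) {
  out <- numeric(0)
  for (i in 0:(D - 1)) {
    for (j in 0:(Dp - 1)) {
      if ((i %in% c_active) && (j %in% p_active)) {
        out <- c(out, i * Dp + j)
      }
    }
  }
  out
}

# O(n^2) all-pairs AUC with explicit tie counting
auc_bruteforce <- function(scores, labels) {
  pos <- which(labels > 0)
  neg <- which(labels < 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# dense loop objective over a plain matrix
objective_bruteforce <- function(w_dense, b, X_dense, y, model, C) {
  n <- nrow(X_dense)
  total <- 0
  for (s in seq_len(n)) {
    m <- y[s] * (sum(X_dense[s, ] * w_dense) + b)
    total <- total + if (grepl("LOG$", model)) log(1 + exp(-m)) else max(0, 1 - m)
  }
  reg <- if (grepl("^L1", model)) sum(abs(w_dense)) else 0.5 * sum(w_dense^2)
  reg + C * total
}

# global minimum of the piecewise-linear L1-hinge objective by exhaustive
# vertex enumeration of the hyperplane arrangement (exact for p <= 3)
l1svm_min_enum <- function(K, C) {
  p <- ncol(K)
  stopifnot(p <= 3)
  H <- rbind(diag(p), K)
  h <- c(rep(0, p), rep(1, nrow(K)))
  obj <- function(w) sum(abs(w)) + C * sum(pmax(0, 1 - as.numeric(K %*% w)))
  best <- obj(rep(0, p))
  idx <- utils::combn(nrow(H), p)
  for (cc in seq_len(ncol(idx))) {
    A <- H[idx[, cc], , drop = FALSE]
    if (abs(det(A)) < 1e-9) next
    best <- min(best, obj(solve(A, h[idx[, cc]])))
  }
  best
}

# optimal L2-hinge objective via the box-constrained dual QP
# (min 1/2 a'Qa - 1'a, 0 <= a <= C; strong duality gives w* = K'a*)
l2svm_min_dual <- function(K, C) {
  n <- nrow(K)
  Q <- as.matrix(K %*% t(K))
  f <- function(a) 0.5 * sum(a * (Q %*% a)) - sum(a)
  g <- function(a) as.numeric(Q %*% a) - 1
  o <- stats::optim(rep(0, n), f, g, method = "L-BFGS-B", lower = 0, upper = C,
                    control = list(maxit = 5000, factr = 1e3))
  w <- as.numeric(t(K) %*% o$par)
  sum(0.5 * w^2) + C * sum(pmax(0, 1 - as.numeric(K %*% w)))
}

# minimum of the L1/L2 logistic objective by smooth optimization
# (split w = u - v for the L1 case; both parts smooth, L-BFGS-B with box)
logreg_min_lbfgs <- function(K, C, penalty) {
  p <- ncol(K)
  if (penalty == "l1") {
    f <- function(uv) {
      w <- uv[1:p] - uv[(p + 1):(2 * p)]
      m <- as.numeric(K %*% w)
      sum(uv) + C * sum(log(1 + exp(-m)))
    }
    g <- function(uv) {
      w <- uv[1:p] - uv[(p + 1):(2 * p)]
      m <- as.numeric(K %*% w)
      gw <- C * as.numeric(t(K) %*% (-stats::plogis(-m)))
      c(1 + gw, 1 - gw)
    }
    o <- stats::optim(rep(0, 2 * p), f, g, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = 5000, factr = 1e3))
  } else {
    f <- function(w) 0.5 * sum(w^2) + C * sum(log(1 + exp(-as.numeric(K %*% w))))
    g <- function(w) w + C * as.numeric(t(K) %*% (-stats::plogis(-as.numeric(K %*% w))))
    o <- stats::optim(rep(0, p), f, g, method = "L-BFGS-B",
                      control = list(maxit = 5000, factr = 1e3))
  }
  o$value
}

# fabricate a design directly from a dense 0/1 matrix (unit-test shortcut)
design_from_matrix <- function(X, y) {
  structure(
    list(X = methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix"),
         y = y, pairs = NULL, space = NULL),
    class = "dti_design"
  )
}

# fabricate a weight vector
make_weights <- function(index, weight, intercept = 0, model = "L1LOG") {
  structure(list(index = as.numeric(index), weight = as.numeric(weight),
                 intercept = intercept, model = model, C = 1,
                 converged = TRUE, iterations = 0L),
            class = "weight_vector")
}

# random fingerprint pair over a small space
random_fingerprints <- function(D = 10, Dp = 12, n_c = 4, n_p = 3) {
  sp <- descriptor_space(sprintf("S%02d", 1:D), sprintf("P%02d", 1:Dp))
  list(
    space = sp,
    c = compound_fingerprint("c", sort(sample(0:(D - 1), n_c)), D),
    p = protein_fingerprint("t", sort(sample(0:(Dp - 1), n_p)), Dp)
  )
}

# small labeled design with a planted separating feature structure
toy_design <- function(seed = 1, n = 40, D = 6, Dp = 5) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * D * Dp, 1, 0.2), n, D * Dp)
    beta <- c(2.5, -2, rep(0, D * Dp - 2))
    y <- ifelse(runif(n) < plogis(as.numeric(X %*% beta) - 0.2), 1, -1)
    if (length(unique(y)) == 1L) y[1:2] <- c(-1, 1)
    design_from_matrix(X, y)
  })
}
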