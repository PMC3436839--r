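#' Training configuration for the regularized linear classifiers
#'
#' The four models combine an L1 or L2 penalty with logistic or hinge loss,
#' all minimizing
#' \deqn{R(w) + C \sum_i loss(y_i f(x_i)),}
#' where `R(w)` is `||w||_1` for L1 models and `(1/2)||w||_2^2` for L2
#' models, the loss is `log(1 + exp(-m))` (LOG) or `max(0, 1 - m)` (SVM),
#' and `C > 0` trades data fit against regularization (the liblinear
#' convention: larger `C`, weaker regularization).
#'
#' @param model one of `"L1LOG"`, `"L1SVM"`, `"L2LOG"`, `"L2SVM"`
#'   (case-insensitive).
#' @param C positive regularization trade-off.
#' @param tolerance positive convergence tolerance (relative objective
#'   change); affects only low-magnitude weights.
#' @param max_iterations iteration cap for the solver.
#' @param seed integer seed for any internal randomization (the solvers are
#'   deterministic; kept for the reproducibility contract).
#' @param fit_intercept fit an unpenalized intercept? Off by default: the
#'   decision function is the pure linear form `w' Phi(C, P)`.
#'
#' @return An object of class `"training_config"`.
#' @export
training_config <- function(model = c("L1LOG", "L1SVM", "L2LOG", "L2SVM"),
                            C = 1, tolerance = 1e-4,
                            max_iterations = 20000L, seed = 1L,
                            fit_intercept = FALSE) {
  model <- toupper(model)
  model <- match.arg(model)
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be positive")
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be positive")
  }
  structure(
    list(model = model, C = C, tolerance = tolerance,
         max_iterations = as.integer(max_iterations),
         seed = as.integer(seed), fit_intercept = isTRUE(fit_intercept)),
    class = "training_config"
  )
}

model_penalty <- function(model) if (startsWith(model, "L1")) "l1" else "l2"
model_loss <- function(model) if (endsWith(model, "LOG")) "log" else "hinge"

# numerically stable log(1 + exp(-m))
log1pexp_neg <- function(m) {
  out <- numeric(length(m))
  big <- m < -33
  out[big] <- -m[big]
  out[!big] <- log1p(exp(-m[!big]))
  out
}

#' Regularized empirical-risk objective of a weight vector
#'
#' Evaluates `R(w) + C * sum_i loss(y_i * (x_i' w + b))` for the model named
#' in `config` on a featurized dataset. The intercept, when present, is not
#' penalized.
#'
#' @param w a [`weight_vector`][train_classifier()].
#' @param design a `"dti_design"` from [featurize_interactions()].
#' @param config a [training_config()].
#' @return The objective value (a single number).
#' @export
objective_value <- function(w, design, config) {
  stopifnot(inherits(w, "weight_vector"), inherits(design, "dti_design"),
            inherits(config, "training_config"))
  if (nrow(design$X) == 0L) stop("empty dataset")
  m <- design$y * (design_scores(w, design))
  loss <- switch(model_loss(config$model),
    log = log1pexp_neg(m),
    hinge = pmax(0, 1 - m)
  )
  reg <- switch(model_penalty(config$model),
    l1 = sum(abs(w$weight)),
    l2 = 0.5 * sum(w$weight^2)
  )
  reg + config$C * sum(loss)
}

design_scores <- function(w, design) {
  sv <- Matrix::sparseVector(x = w$weight, i = w$index + 1,
                             length = ncol(design$X))
  as.numeric(design$X %*% sv) + w$intercept
}

#' Train a regularized linear classifier on tensor pair features
#'
#' Minimizes `R(w) + C * sum_i loss(y_i f(x_i))` over the sparse pair-feature
#' design. `L1LOG` is fitted by coordinate descent through \pkg{glmnet} at
#' the equivalent penalty `lambda = 1/(n*C)`; `L2LOG`, being smooth, by
#' L-BFGS; the hinge models (`L1SVM`, `L2SVM`) by a primal-dual
#' (Chambolle-Pock) iteration that handles the nonsmooth hinge and L1 terms
#' exactly through their proximal maps. All routes are deterministic; pair
#' features that never occur in the data keep weight zero.
#'
#' @param design a `"dti_design"` from [featurize_interactions()]; must
#'   contain both classes.
#' @param config a [training_config()].
#'
#' @return An object of class `"weight_vector"`: fields `index` (0-based
#'   pair-feature indices with nonzero weight), `weight`, `intercept`,
#'   `model`, `C`, `converged`, `iterations` and (when not converged)
#'   `warning`.
#'
#' @examples
#' sp <- descriptor_space(paste0("S", 1:3), paste0("P", 1:2))
#' cfp <- fingerprint_set(list(a = "S1", b = "S2"), "compound",
#'                        declared_labels = sp$substructure_labels)
#' pfp <- fingerprint_set(list(u = "P1", v = "P2"), "protein",
#'                        declared_labels = sp$domain_labels)
#' ds <- interaction_dataset(c("a", "a", "b", "b"), c("u", "v", "u", "v"),
#'                           c(1, 1, -1, -1))
#' dsn <- featurize_interactions(ds, cfp, pfp, sp)
#' w <- train_classifier(dsn, training_config("L1LOG", C = 10))
#' extract_features(w, sp)
#'
#' @export
train_classifier <- function(design, config) {
  stopifnot(inherits(design, "dti_design"), inherits(config, "training_config"))
  y <- design$y
  if (!all(c(-1, 1) %in% y)) stop("training data must contain both classes")
  X <- design$X
  n <- nrow(X)
  # restrict to pair features observed in the data; the rest stay at 0
  nnz_col <- diff(X@p)
  keep <- which(nnz_col > 0L)
  Xo <- X[, keep, drop = FALSE]

  if (length(keep) == 0L && !config$fit_intercept) {
    # no pair feature ever occurs: the zero vector is the minimizer
    return(structure(
      list(index = numeric(0), weight = numeric(0), intercept = 0,
           model = config$model, C = config$C, converged = TRUE,
           iterations = 0L),
      class = "weight_vector"
    ))
  }
  fit <- if (model_loss(config$model) == "log") {
    if (model_penalty(config$model) == "l1") {
      fit_logistic_l1(Xo, y, config)
    } else {
      fit_logistic_l2(Xo, y, config)
    }
  } else {
    fit_hinge(Xo, y, config)
  }

  w <- fit$w
  nz <- which(w != 0)
  res <- structure(
    list(index = as.numeric(keep[nz] - 1), weight = w[nz],
         intercept = fit$intercept, model = config$model, C = config$C,
         converged = fit$converged, iterations = fit$iterations),
    class = "weight_vector"
  )
  if (!fit$converged) {
    res$warning <- sprintf("%s solver stopped at max_iterations = %d",
                           config$model, config$max_iterations)
  }
  res
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf(
    "%s weight vector (C = %g): %d nonzero weights (%d positive), intercept %.4g%s\n",
    x$model, x$C, length(x$weight), sum(x$weight > 0), x$intercept,
    if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}

# glmnet lasso backend: objective/(n*C) recasts ||w||_1 + C*sum(loss) as
# (1/n)*sum(loss) + lambda*||w||_1 with lambda = 1/(n*C).
fit_logistic_l1 <- function(Xo, y, config) {
  n <- nrow(Xo)
  pad <- max(0L, 2L - ncol(Xo))  # glmnet needs >= 2 columns
  if (pad > 0L) {
    Xo <- cbind(Xo, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(n, pad)))
  }
  lam <- 1 / (n * config$C)
  # warm-start path descending to the target penalty
  path <- lam * c(10000, 1000, 300, 100, 30, 10, 3, 1)
  fit <- glmnet::glmnet(
    Xo, factor(y, levels = c(-1, 1)), family = "binomial",
    alpha = 1, lambda = path, standardize = FALSE,
    intercept = config$fit_intercept,
    thresh = min(1e-7, config$tolerance * 1e-3),
    maxit = max(config$max_iterations, 1e5)
  )
  beta <- coef(fit, s = lam, exact = FALSE)
  w <- as.numeric(beta)[-1L]
  if (pad > 0L) w <- w[seq_len(length(w) - pad)]
  list(w = w, intercept = as.numeric(beta)[1L],
       converged = fit$jerr == 0, iterations = as.integer(fit$npasses))
}

# ridge logistic is smooth, so L-BFGS on (1/2)||w||^2 + C*sum(log1pexp(-m))
# is direct and fast; the intercept rides along unpenalized.
fit_logistic_l2 <- function(Xo, y, config) {
  n <- nrow(Xo)
  K <- as(Matrix::Diagonal(x = y) %*% Xo, "CsparseMatrix")
  if (config$fit_intercept) K <- cbind(K, y)
  Kt <- Matrix::t(K)
  pk <- ncol(K)
  C <- config$C
  has_b <- config$fit_intercept
  fn <- function(w) {
    m <- as.numeric(K %*% w)
    wpen <- if (has_b) w[-pk] else w
    0.5 * sum(wpen^2) + C * sum(log1pexp_neg(m))
  }
  gr <- function(w) {
    m <- as.numeric(K %*% w)
    g <- as.numeric(Kt %*% (-plogis(-m))) * C
    if (has_b) g + c(w[-pk], 0) else g + w
  }
  o <- stats::optim(numeric(pk), fn, gr, method = "L-BFGS-B",
                    control = list(maxit = config$max_iterations,
                                   factr = 1e7))
  if (has_b) {
    list(w = o$par[-pk], intercept = o$par[pk],
         converged = o$convergence == 0, iterations = o$counts[["function"]])
  } else {
    list(w = o$par, intercept = 0,
         converged = o$convergence == 0, iterations = o$counts[["function"]])
  }
}

# Chambolle-Pock primal-dual iteration for hinge loss with L1 or L2 penalty.
# min_w R(w) + C*sum(max(0, 1 - (Kw)_i)) with K = diag(y) X; the dual prox
# is a per-sample clip, the primal prox is soft-thresholding (L1) or scaling
# (L2). The intercept, when fitted, rides along as an unpenalized column.
fit_hinge <- function(Xo, y, config) {
  n <- nrow(Xo)
  p <- ncol(Xo)
  K <- Matrix::Diagonal(x = y) %*% Xo
  if (config$fit_intercept) K <- cbind(K, y)
  K <- as(K, "CsparseMatrix")
  Kt <- Matrix::t(K)
  pk <- ncol(K)
  # spectral norm by power iteration fixes the step sizes
  v <- rep(1 / sqrt(pk), pk)
  nv <- 1
  for (it in 1:100) {
    u <- as.numeric(K %*% v)
    v2 <- as.numeric(Kt %*% u)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v <- v2 / nv
  }
  step <- 1 / sqrt(max(nv, .Machine$double.eps))
  C <- config$C
  l1 <- model_penalty(config$model) == "l1"
  objective <- function(w) {
    m <- as.numeric(K %*% w)
    wpen <- if (config$fit_intercept) w[-pk] else w
    reg <- if (l1) sum(abs(wpen)) else 0.5 * sum(wpen^2)
    reg + C * sum(pmax(0, 1 - m))
  }
  w <- numeric(pk)
  wbar <- w
  u <- numeric(n)
  best <- objective(w)
  check_every <- 50L
  stall <- 0L
  iters <- 0L
  converged <- FALSE
  while (iters < config$max_iterations) {
    iters <- iters + 1L
    u <- pmin(0, pmax(-C, u + step * as.numeric(K %*% wbar) - step))
    wn <- w - step * as.numeric(Kt %*% u)
    if (l1) {
      thr <- rep(step, pk)
      if (config$fit_intercept) thr[pk] <- 0
      wn <- sign(wn) * pmax(0, abs(wn) - thr)
    } else {
      sc <- rep(1 / (1 + step), pk)
      if (config$fit_intercept) sc[pk] <- 1
      wn <- wn * sc
    }
    wbar <- 2 * wn - w
    w <- wn
    if (iters %% check_every == 0L) {
      o <- objective(w)
      if (o > best - config$tolerance * 0.01 * (1 + abs(best))) {
        stall <- stall + 1L
      } else {
        stall <- 0L
      }
      best <- min(best, o)
      if (stall >= 5L) {
        converged <- TRUE
        break
      }
    }
  }
  if (config$fit_intercept) {
    list(w = w[-pk], intercept = w[pk], converged = converged,
         iterations = iters)
  } else {
    list(w = w, intercept = 0, converged = converged, iterations = iters)
  }
}

#' Score a drug-target pair with a trained weight vector
#'
#' The decision value is `f(C, P) = w' Phi(C, P) + b`, the sum of the weights
#' of the pair features active in `x` plus the intercept; its sign is the
#' predicted class.
#'
#' @param w a [`weight_vector`][train_classifier()].
#' @param x a `"pair_feature_vector"` from [tensor_featurize()].
#' @return The decision value (a single number).
#' @export
predict_score <- function(w, x) {
  stopifnot(inherits(w, "weight_vector"), inherits(x, "pair_feature_vector"))
  hit <- match(as.numeric(x), w$index)
  sum(w$weight[hit[!is.na(hit)]]) + w$intercept
}

#' @export
#' @param object a `"weight_vector"`.
#' @param newdata a `"dti_design"`.
#' @param ... unused.
#' @rdname predict_score
predict.weight_vector <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "dti_design"))
  design_scores(object, newdata)
}

#' Pairwise kernel between two drug-target pairs
#'
#' The inner product of two tensor-product pair fingerprints factorizes into
#' the product of the compound-fingerprint and protein-fingerprint inner
#' products:
#' `<Phi(C1,P1), Phi(C2,P2)> = |act(C1) n act(C2)| * |act(P1) n act(P2)|`.
#' This is the kernel that pairwise kernel-SVM approaches evaluate; it is
#' exposed so external kernel machines can be driven for comparison without
#' materializing the tensor space.
#'
#' @param c1,c2 `"compound_fingerprint"` objects over the same vocabulary.
#' @param p1,p2 `"protein_fingerprint"` objects over the same vocabulary.
#' @return A non-negative integer.
#' @export
pairwise_kernel <- function(c1, p1, c2, p2) {
  stopifnot(inherits(c1, "compound_fingerprint"),
            inherits(c2, "compound_fingerprint"),
            inherits(p1, "protein_fingerprint"),
            inherits(p2, "protein_fingerprint"))
  if (c1$n != c2$n) stop("compound fingerprints live in different spaces")
  if (p1$n != p2$n) stop("protein fingerprints live in different spaces")
  length(intersect(c1$active, c2$active)) *
    length(intersect(p1$active, p2$active))
}
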