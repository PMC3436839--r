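#' Negative sampling configuration
#'
#' @param ratio negatives per positive: a positive number, or `"ALL"` for
#'   every candidate non-interacting pair.
#' @param seed integer seed; sampling is bit-reproducible given the seed
#'   (and seed-independent for `"ALL"`).
#' @return An object of class `"negative_sampling_config"`.
#' @export
negative_sampling_config <- function(ratio, seed = 1L) {
  if (is.character(ratio)) {
    if (toupper(ratio) != "ALL") stop("ratio must be a positive number or 'ALL'")
    ratio <- "ALL"
  } else if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) {
    stop("ratio must be a positive number or 'ALL'")
  }
  structure(list(ratio = ratio, seed = as.integer(seed)),
            class = "negative_sampling_config")
}

#' Sample presumed non-interacting pairs as negatives
#'
#' Treats every (drug, target) combination absent from the positives as a
#' candidate non-interaction and draws a uniform sample without replacement
#' of size `min(ratio * n_positives, pool size)`; `"ALL"` returns the whole
#' pool. Sampled pairs get label -1 and are disjoint from the positives by
#' construction.
#'
#' @param positives an [interaction_dataset()] of +1 pairs.
#' @param config a [negative_sampling_config()].
#' @param compound_ids,protein_ids optional id universes; default to the ids
#'   occurring in `positives`.
#' @return An [interaction_dataset()] of -1 pairs.
#' @export
sample_negatives <- function(positives, config,
                             compound_ids = NULL, protein_ids = NULL) {
  stopifnot(inherits(positives, "interaction_dataset"),
            inherits(config, "negative_sampling_config"))
  if (nrow(positives) == 0L) stop("positives must be non-empty")
  if (any(positives$label != 1)) stop("positives must all carry label +1")
  cids <- if (is.null(compound_ids)) {
    sort(unique(positives$compound_id), method = "radix")
  } else {
    as.character(compound_ids)
  }
  pids <- if (is.null(protein_ids)) {
    sort(unique(positives$protein_id), method = "radix")
  } else {
    as.character(protein_ids)
  }
  nd <- length(cids)
  nt <- length(pids)
  # flat pair keys over the id grid; positives knocked out of the pool
  pos_key <- (match(positives$compound_id, cids) - 1) * nt +
    match(positives$protein_id, pids)
  if (anyNA(pos_key)) stop("positives contain ids outside the given universes")
  pool <- setdiff(seq_len(nd * nt), pos_key)
  if (length(pool) == 0L) stop("no candidate negative pairs: the grid is saturated")
  if (identical(config$ratio, "ALL")) {
    take <- pool
  } else {
    size <- min(round(config$ratio * nrow(positives)), length(pool))
    take <- withr::with_seed(config$seed, sample(pool, size))
  }
  d <- (take - 1) %/% nt + 1
  t_ <- (take - 1) %% nt + 1
  interaction_dataset(cids[d], pids[t_], rep(-1, length(take)))
}

#' Cross-validation plan
#'
#' @param mode `"pairwise"` (folds partition labeled pairs; a test pair's
#'   drug and target may train with other partners) or `"blockwise"` (folds
#'   partition drugs and targets; test pairs involve only held-out drugs AND
#'   held-out targets -- the cold-start scenario).
#' @param k number of folds (>= 2).
#' @param repeats number of independent repetitions (>= 1).
#' @param seed integer root seed.
#' @return An object of class `"cv_plan"`.
#' @export
cv_plan <- function(mode = c("pairwise", "blockwise"), k = 5L, repeats = 5L,
                    seed = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  repeats <- as.integer(repeats)
  if (k < 2L) stop("k must be at least 2")
  if (repeats < 1L) stop("repeats must be at least 1")
  structure(list(mode = mode, k = k, repeats = repeats, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Pair-wise cross-validation folds
#'
#' Randomly partitions the labeled pairs into `k` folds of sizes differing
#' by at most one; each fold in turn is the test set and the rest train.
#'
#' @param data an [interaction_dataset()] (or anything with rows).
#' @param plan a [cv_plan()]; only `k` and `seed` are used.
#' @return A list of `k` elements, each `list(train = , test = )` of row
#'   indices, with class `"cv_folds"`.
#' @export
pairwise_cv_split <- function(data, plan) {
  stopifnot(inherits(plan, "cv_plan"))
  n <- nrow(data)
  if (n < plan$k) stop(sprintf("need at least k = %d pairs, got %d", plan$k, n))
  fold <- withr::with_seed(plan$seed,
                           sample(rep(seq_len(plan$k), length.out = n)))
  out <- lapply(seq_len(plan$k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
  structure(out, class = "cv_folds", mode = "pairwise")
}

#' Block-wise (cold-start) cross-validation folds
#'
#' Randomly partitions drugs into `k` folds and targets into `k` folds.
#' Fold `f` tests every labeled pair whose drug is in drug-fold `f` AND
#' whose target is in target-fold `f`, and trains on pairs whose drug and
#' target are both outside fold `f`. Pairs with exactly one member in fold
#' `f` are used in neither, so no test drug and no test target ever appears
#' in training (the cold-start contract).
#'
#' @param data an [interaction_dataset()].
#' @param plan a [cv_plan()]; only `k` and `seed` are used.
#' @return A `"cv_folds"` list as in [pairwise_cv_split()]; folds with zero
#'   test pairs are flagged in the `"warnings"` attribute.
#' @export
blockwise_cv_split <- function(data, plan) {
  stopifnot(inherits(data, "interaction_dataset"), inherits(plan, "cv_plan"))
  drugs <- sort(unique(data$compound_id), method = "radix")
  targets <- sort(unique(data$protein_id), method = "radix")
  if (length(drugs) < plan$k || length(targets) < plan$k) {
    stop(sprintf("need at least k = %d drugs and targets", plan$k))
  }
  fold_assign <- withr::with_seed(plan$seed, list(
    drug = sample(rep(seq_len(plan$k), length.out = length(drugs))),
    target = sample(rep(seq_len(plan$k), length.out = length(targets)))
  ))
  df <- fold_assign$drug[match(data$compound_id, drugs)]
  tf <- fold_assign$target[match(data$protein_id, targets)]
  warnings <- character(0)
  out <- lapply(seq_len(plan$k), function(f) {
    list(train = which(df != f & tf != f), test = which(df == f & tf == f))
  })
  empty <- which(vapply(out, function(x) length(x$test) == 0L, logical(1)))
  if (length(empty) > 0L) {
    warnings <- sprintf("fold %d has zero test pairs", empty)
  }
  structure(out, class = "cv_folds", mode = "blockwise",
            drug_folds = fold_assign$drug, target_folds = fold_assign$target,
            warnings = warnings)
}

#' Area under the ROC curve
#'
#' Computed as the tie-corrected Mann-Whitney statistic
#' `P(score+ > score-) + 0.5 * P(score+ = score-)` via mean ranks: 1 is a
#' perfect inference, 0.5 a random one. Invariant under strictly increasing
#' transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels +1/-1 labels; both classes must be present.
#' @return The AUC, in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pos <- labels > 0
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both a positive and a negative class")
  }
  r <- rank(scores)  # average ranks give the tie correction
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Select the regularization trade-off C by inner cross-validation
#'
#' Fits the model at every grid value on inner pair-wise folds and picks the
#' `C` maximizing mean inner AUC; exact ties go to the smallest `C`
#' (strongest regularization).
#'
#' @param design a `"dti_design"` with both classes.
#' @param model model name, as in [training_config()].
#' @param C_grid numeric vector of candidate values.
#' @param plan a [cv_plan()] for the inner folds (`k`, `seed` used).
#' @param ... further arguments passed to [training_config()].
#' @return A list with the chosen `C` and the grid `table` of mean AUCs.
#' @export
select_hyperparameter <- function(design, model, C_grid, plan, ...) {
  stopifnot(inherits(design, "dti_design"))
  if (length(C_grid) == 0L) stop("empty C grid")
  C_grid <- sort(as.numeric(C_grid))
  folds <- pairwise_cv_split(data.frame(row = seq_along(design$y)), plan)
  mean_auc <- vapply(C_grid, function(C) {
    aucs <- vapply(folds, function(f) {
      tr <- design_subset(design, f$train)
      te <- design_subset(design, f$test)
      if (!all(c(-1, 1) %in% tr$y) || !all(c(-1, 1) %in% te$y)) {
        return(NA_real_)
      }
      w <- train_classifier(tr, training_config(model, C = C, ...))
      roc_auc(predict(w, te), te$y)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which(mean_auc == max(mean_auc))[1L]  # ascending grid: ties -> smallest C
  list(C = C_grid[best],
       table = data.frame(C = C_grid, mean_auc = mean_auc))
}

#' Run the full cross-validated evaluation grid
#'
#' For every repetition, negative-sampling ratio and model: samples
#' negatives (before fold splitting, so folds carry both classes at the
#' global ratio), splits folds by the plan's mode, trains on each training
#' fold, scores its test fold, and records per-fold AUCs plus the count of
#' positively weighted pair features of each fitted model. Repetitions
#' re-randomize both folds and negative samples from seeds derived from the
#' plan's root seed, so the whole grid is reproducible from one integer.
#'
#' @param positives an [interaction_dataset()] of gold-standard +1 pairs.
#' @param compounds,proteins [fingerprint_set()]s resolving every id.
#' @param models character vector of model names.
#' @param ratios vector of negative ratios (numbers and/or `"ALL"`).
#' @param plan a [cv_plan()].
#' @param C fixed regularization trade-off used for every model (default 1),
#'   unless `C_grid` is given.
#' @param C_grid optional grid; when given, `C` is re-selected by
#'   [select_hyperparameter()] on each training fold's data.
#' @param ... further arguments passed to [training_config()].
#'
#' @return A data frame of class `"evaluation_result"` with one row per
#'   (mode, model, ratio): `mean_auc`, `sd_auc` (across repetitions),
#'   `n_features_positive` (mean count of positive weights across fits).
#'   The attribute `"details"` holds every per-fold AUC.
#' @export
run_experiment <- function(positives, compounds, proteins, models, ratios,
                           plan, C = 1, C_grid = NULL, ...) {
  stopifnot(inherits(positives, "interaction_dataset"),
            inherits(plan, "cv_plan"))
  models <- toupper(models)
  details <- list()
  for (ratio in ratios) {
    ratio_lab <- if (is.character(ratio)) toupper(ratio) else ratio
    for (r in seq_len(plan$repeats)) {
      neg_seed <- derive_seed(plan$seed, "negatives", ratio_lab, "repeat", r)
      negatives <- sample_negatives(
        positives, negative_sampling_config(ratio, seed = neg_seed)
      )
      data <- interaction_dataset(
        c(positives$compound_id, negatives$compound_id),
        c(positives$protein_id, negatives$protein_id),
        c(positives$label, negatives$label)
      )
      design <- featurize_interactions(data, compounds, proteins)
      fold_seed <- derive_seed(plan$seed, "folds", ratio_lab, "repeat", r)
      fplan <- cv_plan(plan$mode, k = plan$k, repeats = 1L, seed = fold_seed)
      folds <- if (plan$mode == "pairwise") {
        pairwise_cv_split(data, fplan)
      } else {
        blockwise_cv_split(data, fplan)
      }
      for (model in models) {
        for (f in seq_along(folds)) {
          tr <- design_subset(design, folds[[f]]$train)
          te <- design_subset(design, folds[[f]]$test)
          if (length(folds[[f]]$test) == 0L ||
              !all(c(-1, 1) %in% tr$y) || !all(c(-1, 1) %in% te$y)) {
            next
          }
          C_use <- if (is.null(C_grid)) {
            C
          } else {
            inner <- cv_plan("pairwise", k = min(3L, plan$k), repeats = 1L,
                             seed = derive_seed(fold_seed, "inner", model, f))
            select_hyperparameter(tr, model, C_grid, inner, ...)$C
          }
          w <- train_classifier(tr, training_config(model, C = C_use, ...))
          details[[length(details) + 1L]] <- data.frame(
            mode = plan$mode, model = model, ratio = as.character(ratio_lab),
            repeat_ = r, fold = f, C = C_use,
            auc = roc_auc(predict(w, te), te$y),
            n_features_positive = sum(w$weight > 0),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  details <- do.call(rbind, details)
  if (is.null(details)) stop("no evaluable folds in the experiment grid")
  key <- interaction(details$mode, details$model, details$ratio, drop = TRUE)
  rows <- lapply(split(details, key), function(d) {
    rep_means <- tapply(d$auc, d$repeat_, mean)
    data.frame(
      mode = d$mode[1L], model = d$model[1L], ratio = d$ratio[1L],
      mean_auc = mean(d$auc),
      sd_auc = if (length(rep_means) > 1L) sd(rep_means) else NA_real_,
      n_features_positive = mean(d$n_features_positive),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("evaluation_result", "data.frame"),
            details = details)
}

#' Write an evaluation result table to TSV
#'
#' @param result an [`evaluation_result`][run_experiment()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(result, path) {
  stopifnot(inherits(result, "evaluation_result"))
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
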