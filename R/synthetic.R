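#' Configuration of the synthetic chemogenomic data generator
#'
#' The generator emulates the three tables a chemogenomic study consumes:
#' binary compound substructure fingerprints, binary protein domain
#' fingerprints, and a gold standard of interacting pairs. Interactions are
#' drawn from a logistic model whose log-odds increase by `effect` for every
#' planted (substructure, domain) association co-active in a pair, so the
#' planted associations are the ground-truth chemogenomic features a sparse
#' classifier should recover.
#'
#' Defaults describe a mid-sized benchmark: 200 drugs x 150 targets, 100
#' substructure and 80 domain descriptors active independently with
#' probability 0.05, 20 planted associations of strength 3.0 on the log-odds
#' scale, and a baseline interaction probability of 2%
#' (`bias = qlogis(0.02)`).
#'
#' @param n_drugs,n_targets entity counts.
#' @param D,D_prime descriptor vocabulary sizes.
#' @param p_sub,p_dom per-descriptor activation probabilities in (0, 1).
#' @param K_true number of planted (substructure, domain) associations.
#' @param effect log-odds increment per co-active planted association
#'   (>= 0; 0 collapses the model to a constant interaction probability).
#' @param bias baseline interaction log-odds.
#' @param seed integer root seed; all randomness flows from it through named
#'   substreams (fingerprints, planted truth, interaction draws).
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_drugs = 200L, n_targets = 150L,
                             D = 100L, D_prime = 80L,
                             p_sub = 0.05, p_dom = 0.05,
                             K_true = 20L, effect = 3.0,
                             bias = qlogis(0.02), seed = 1L) {
  if (p_sub <= 0 || p_sub >= 1 || p_dom <= 0 || p_dom >= 1) {
    stop("activation probabilities must lie in (0, 1)")
  }
  if (K_true > D * D_prime) stop("K_true exceeds the pair-feature space")
  if (effect < 0) stop("effect must be non-negative")
  structure(
    list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
         D = as.integer(D), D_prime = as.integer(D_prime),
         p_sub = p_sub, p_dom = p_dom, K_true = as.integer(K_true),
         effect = effect, bias = bias, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic chemogenomic dataset with planted associations
#'
#' Fingerprint bits are independent Bernoulli draws. For each (drug, target)
#' pair the interaction probability is
#' `plogis(bias + effect * n_coactive_planted)`, and pairs drawn as
#' interacting form the gold-standard positives. Fully deterministic given
#' the config seed.
#'
#' @param config a [generator_config()].
#' @return A list of class `"synthetic_dataset"`: `compounds` and `proteins`
#'   ([fingerprint_set()]s over the full declared vocabularies), `space`,
#'   `positives` (an [interaction_dataset()]), `truth` (data frame of
#'   planted associations: `sub_index`, `dom_index`, `substructure`,
#'   `domain`, `weight`), `prob` (the n_drugs x n_targets interaction
#'   probability matrix) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  sub_labels <- sprintf("SUB%03d", seq_len(config$D))
  dom_labels <- sprintf("PF%05d", seq_len(config$D_prime))
  drug_ids <- sprintf("DRUG%04d", seq_len(config$n_drugs))
  target_ids <- sprintf("PROT%04d", seq_len(config$n_targets))
  space <- descriptor_space(sub_labels, dom_labels)

  Fc <- withr::with_seed(
    derive_seed(config$seed, "compound_fingerprints"),
    matrix(rbinom(config$n_drugs * config$D, 1L, config$p_sub),
           config$n_drugs, config$D)
  )
  Fp <- withr::with_seed(
    derive_seed(config$seed, "protein_fingerprints"),
    matrix(rbinom(config$n_targets * config$D_prime, 1L, config$p_dom),
           config$n_targets, config$D_prime)
  )
  planted <- withr::with_seed(
    derive_seed(config$seed, "planted_truth"),
    sample(config$D * config$D_prime, config$K_true) - 1
  )
  ij <- unpair_index(planted, space)

  # log-odds: bias + effect * (# planted associations co-active in the pair)
  eta <- matrix(config$bias, config$n_drugs, config$n_targets)
  for (k in seq_len(config$K_true)) {
    eta <- eta + config$effect *
      outer(Fc[, ij[k, "i"] + 1L], Fp[, ij[k, "j"] + 1L])
  }
  prob <- plogis(eta)
  ymat <- withr::with_seed(
    derive_seed(config$seed, "interaction_draws"),
    matrix(rbinom(length(prob), 1L, prob), nrow(prob), ncol(prob))
  )
  pos <- which(ymat == 1L, arr.ind = TRUE)
  if (nrow(pos) == 0L) {
    stop("no positive interactions generated; increase bias or effect")
  }

  compounds <- fingerprint_set(
    stats::setNames(apply(Fc == 1L, 1L, function(r) sub_labels[r],
                          simplify = FALSE), drug_ids),
    role = "compound", declared_labels = sub_labels
  )
  proteins <- fingerprint_set(
    stats::setNames(apply(Fp == 1L, 1L, function(r) dom_labels[r],
                          simplify = FALSE), target_ids),
    role = "protein", declared_labels = dom_labels
  )
  truth <- data.frame(
    sub_index = as.integer(ij[, "i"]), dom_index = as.integer(ij[, "j"]),
    substructure = sub_labels[ij[, "i"] + 1L],
    domain = dom_labels[ij[, "j"] + 1L],
    weight = config$effect, stringsAsFactors = FALSE
  )
  structure(
    list(
      compounds = compounds, proteins = proteins, space = space,
      positives = interaction_dataset(drug_ids[pos[, 1L]],
                                      target_ids[pos[, 2L]]),
      truth = truth, prob = prob, config = config
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic dataset: %d drugs x %d targets, %d positives (rate %.3f), %d planted associations\n",
    x$config$n_drugs, x$config$n_targets, nrow(x$positives),
    nrow(x$positives) / (x$config$n_drugs * x$config$n_targets),
    x$config$K_true
  ))
  invisible(x)
}

#' Precision and recall of extracted features against the planted truth
#'
#' Compares the top `top_k` extracted (substructure, domain) features with
#' the planted associations. Precision divides by `min(top_k,
#' n_extracted)`; recall divides by the number of planted associations. An
#' empty extraction scores (0, 0).
#'
#' @param extracted a [`chemogenomic_features`][extract_features()] table.
#' @param truth the `truth` data frame of a [generate_dataset()] result.
#' @param top_k number of top-ranked features to consider (>= 1).
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
recovery_score <- function(extracted, truth, top_k = nrow(truth)) {
  stopifnot(is.data.frame(extracted), is.data.frame(truth))
  if (top_k < 1L) stop("top_k must be at least 1")
  if (nrow(extracted) == 0L) {
    return(c(precision = 0, recall = 0))
  }
  top <- extracted[seq_len(min(top_k, nrow(extracted))), , drop = FALSE]
  key <- function(d) paste(d$substructure, d$domain, sep = "\r")
  hits <- sum(key(top) %in% key(truth))
  c(precision = hits / min(top_k, nrow(extracted)),
    recall = hits / nrow(truth))
}

#' Write the synthetic tables to a directory
#'
#' Produces the three analysis inputs (`compounds.tsv`, `proteins.tsv`,
#' `interactions.tsv`) plus `truth.tsv` with the planted associations.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fingerprints(dataset$compounds, file.path(dir, "compounds.tsv"))
  write_fingerprints(dataset$proteins, file.path(dir, "proteins.tsv"))
  write_interactions(dataset$positives, file.path(dir, "interactions.tsv"))
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
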