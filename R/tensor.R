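#' Tensor-product featurization of a drug-target pair
#'
#' The pair fingerprint of compound C and protein P is the tensor (outer)
#' product of the two binary fingerprints: pair feature `(i, j)` is active
#' exactly when substructure `i` is present in C and domain `j` is present in
#' P. The result is a sparse vector in the `D * D_prime`-dimensional pair
#' space, with `|active(C)| * |active(P)|` active entries, indexed by
#' [pair_index()].
#'
#' @param c a `"compound_fingerprint"` (see [compound_fingerprint()]).
#' @param p a `"protein_fingerprint"`.
#' @param space a [descriptor_space()]; fingerprint vocabulary sizes must
#'   match `space$D` and `space$D_prime`.
#'
#' @return An object of class `"pair_feature_vector"`: a sorted numeric
#'   vector of 0-based active pair-feature indices with attributes `D` and
#'   `D_prime`.
#'
#' @examples
#' sp <- descriptor_space(paste0("S", 1:4), paste0("P", 1:3))
#' cfp <- compound_fingerprint("d1", c(0L, 2L), sp$D)
#' pfp <- protein_fingerprint("t1", 1L, sp$D_prime)
#' tensor_featurize(cfp, pfp, sp)
#'
#' @export
tensor_featurize <- function(c, p, space) {
  stopifnot(inherits(c, "compound_fingerprint"),
            inherits(p, "protein_fingerprint"),
            inherits(space, "descriptor_space"))
  if (c$n != space$D) {
    stop(sprintf("compound fingerprint dimension %d != space D = %d",
                 c$n, space$D))
  }
  if (p$n != space$D_prime) {
    stop(sprintf("protein fingerprint dimension %d != space D' = %d",
                 p$n, space$D_prime))
  }
  k <- if (length(c$active) == 0L || length(p$active) == 0L) {
    numeric(0)
  } else {
    sort(as.vector(outer(as.numeric(c$active) * space$D_prime,
                         as.numeric(p$active), `+`)))
  }
  structure(k, D = space$D, D_prime = space$D_prime,
            class = "pair_feature_vector")
}

#' @export
print.pair_feature_vector <- function(x, ...) {
  cat(sprintf("pair feature vector: %d active of %.0f (D=%d x D'=%d)\n",
              length(x), as.numeric(attr(x, "D")) * attr(x, "D_prime"),
              attr(x, "D"), attr(x, "D_prime")))
  invisible(x)
}

#' Build the sparse design matrix for a labeled interaction dataset
#'
#' Featurizes every (compound, protein) pair in `data` with
#' [tensor_featurize()] and stacks the results into one sparse 0/1 matrix
#' with `D * D_prime` columns (column `k + 1` holds pair feature `k`).
#'
#' @param data an [interaction_dataset()]; every id must resolve to a
#'   fingerprint.
#' @param compounds a compound [fingerprint_set()].
#' @param proteins a protein [fingerprint_set()].
#' @param space optional [descriptor_space()]; defaults to
#'   [combined_space()] of the two sets.
#'
#' @return An object of class `"dti_design"`: a list with the sparse design
#'   matrix `X` (`dgCMatrix`, one row per pair), the label vector `y` (+1/-1),
#'   the `pairs` data frame and the `space`.
#' @export
featurize_interactions <- function(data, compounds, proteins, space = NULL) {
  stopifnot(inherits(data, "interaction_dataset"))
  if (is.null(space)) space <- combined_space(compounds, proteins)
  miss_c <- setdiff(unique(data$compound_id), compounds$ids)
  if (length(miss_c) > 0L) {
    stop("interaction compounds without fingerprints: ",
         paste(utils::head(miss_c, 5L), collapse = ", "))
  }
  miss_p <- setdiff(unique(data$protein_id), proteins$ids)
  if (length(miss_p) > 0L) {
    stop("interaction proteins without fingerprints: ",
         paste(utils::head(miss_p, 5L), collapse = ", "))
  }
  if (length(compounds$labels) != space$D ||
      length(proteins$labels) != space$D_prime) {
    stop("fingerprint vocabularies do not match the descriptor space")
  }
  n <- nrow(data)
  Dp <- space$D_prime
  ci <- match(data$compound_id, compounds$ids)
  pi_ <- match(data$protein_id, proteins$ids)
  cols <- vector("list", n)
  for (r in seq_len(n)) {
    a <- compounds$active[[ci[r]]]
    b <- proteins$active[[pi_[r]]]
    if (length(a) > 0L && length(b) > 0L) {
      cols[[r]] <- as.vector(outer(as.numeric(a) * Dp, as.numeric(b), `+`))
    } else {
      cols[[r]] <- numeric(0)
    }
  }
  nnz <- lengths(cols)
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(n), nnz),
    j = unlist(cols, use.names = FALSE) + 1,
    x = 1,
    dims = c(n, space$D * space$D_prime)
  )
  structure(list(X = X, y = data$label, pairs = data, space = space),
            class = "dti_design")
}

#' @export
print.dti_design <- function(x, ...) {
  cat(sprintf(
    "featurized interactions: %d pairs (%d+, %d-) x %s pair features, %.0f nonzeros\n",
    nrow(x$X), sum(x$y > 0), sum(x$y < 0),
    format(ncol(x$X), big.mark = ","), length(x$X@x)
  ))
  invisible(x)
}

# subset rows of a design, keeping class and metadata
design_subset <- function(design, rows) {
  structure(
    list(X = design$X[rows, , drop = FALSE],
         y = design$y[rows],
         pairs = design$pairs[rows, , drop = FALSE],
         space = design$space),
    class = "dti_design"
  )
}
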