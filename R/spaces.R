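#' Descriptor space for compound substructures and protein domains
#'
#' A descriptor space fixes the dimensions of the two fingerprint vocabularies:
#' `D` compound substructure descriptors (e.g. PubChem substructure keys such
#' as `"SUB158"`) and `D_prime` protein domain descriptors (e.g. PFAM
#' accessions such as `"PF00106"`). Pair features live in the tensor-product
#' space of dimension `D * D_prime`.
#'
#' @param substructure_labels character vector of unique substructure names.
#' @param domain_labels character vector of unique domain names.
#'
#' @return An object of class `"descriptor_space"` with fields `D`, `D_prime`,
#'   `substructure_labels` and `domain_labels`.
#'
#' @examples
#' sp <- descriptor_space(c("SUB1", "SUB2"), c("PF00001", "PF00002", "PF00003"))
#' sp$D * sp$D_prime  # dimension of the pair-feature space
#'
#' @export
descriptor_space <- function(substructure_labels, domain_labels) {
  substructure_labels <- as.character(substructure_labels)
  domain_labels <- as.character(domain_labels)
  if (length(substructure_labels) == 0L || length(domain_labels) == 0L) {
    stop("descriptor space needs at least one substructure and one domain label")
  }
  if (anyDuplicated(substructure_labels)) {
    stop("duplicate substructure labels in descriptor space")
  }
  if (anyDuplicated(domain_labels)) {
    stop("duplicate domain labels in descriptor space")
  }
  structure(
    list(
      D = length(substructure_labels),
      D_prime = length(domain_labels),
      substructure_labels = substructure_labels,
      domain_labels = domain_labels
    ),
    class = "descriptor_space"
  )
}

#' @export
print.descriptor_space <- function(x, ...) {
  cat(sprintf(
    "descriptor space: %d substructures x %d domains = %s pair features\n",
    x$D, x$D_prime, format(x$D * x$D_prime, big.mark = ",")
  ))
  invisible(x)
}

#' Map a (substructure, domain) index pair to a pair-feature index
#'
#' Pair features are laid out compound-major: the pair feature for
#' substructure `i` and domain `j` (both 0-based) has index
#' `k = i * D_prime + j`, giving indices in `[0, D * D_prime)`.
#' [unpair_index()] is the inverse.
#'
#' @param i 0-based substructure index (vectorized), in `[0, D)`.
#' @param j 0-based domain index (vectorized), in `[0, D_prime)`.
#' @param space a [descriptor_space()].
#'
#' @return Numeric vector of 0-based pair-feature indices.
#'
#' @examples
#' sp <- descriptor_space(paste0("S", 1:5), paste0("P", 1:7))
#' pair_index(0, 0, sp)  # 0
#' pair_index(1, 0, sp)  # 7
#' unpair_index(pair_index(2, 3, sp), sp)
#'
#' @export
pair_index <- function(i, j, space) {
  stopifnot(inherits(space, "descriptor_space"))
  i <- as.numeric(i)
  j <- as.numeric(j)
  if (any(i < 0 | i >= space$D) || any(i != floor(i))) {
    stop(sprintf("substructure index out of range [0, %d)", space$D))
  }
  if (any(j < 0 | j >= space$D_prime) || any(j != floor(j))) {
    stop(sprintf("domain index out of range [0, %d)", space$D_prime))
  }
  i * space$D_prime + j
}

#' @rdname pair_index
#' @param k 0-based pair-feature index (vectorized), in `[0, D * D_prime)`.
#' @return For `unpair_index`, a two-column matrix with columns `i`
#'   (substructure index) and `j` (domain index).
#' @export
unpair_index <- function(k, space) {
  stopifnot(inherits(space, "descriptor_space"))
  k <- as.numeric(k)
  if (any(k < 0 | k >= space$D * space$D_prime) || any(k != floor(k))) {
    stop(sprintf("pair-feature index out of range [0, %.0f)", space$D * space$D_prime))
  }
  cbind(i = k %/% space$D_prime, j = k %% space$D_prime)
}

#' Decode pair-feature indices to substructure and domain labels
#'
#' @param k 0-based pair-feature indices.
#' @param space a [descriptor_space()].
#' @return A data frame with columns `substructure` and `domain`.
#' @export
pair_labels <- function(k, space) {
  ij <- unpair_index(k, space)
  data.frame(
    substructure = space$substructure_labels[ij[, "i"] + 1L],
    domain = space$domain_labels[ij[, "j"] + 1L],
    stringsAsFactors = FALSE
  )
}
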