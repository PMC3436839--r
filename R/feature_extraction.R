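#' Extract ranked chemogenomic features from a trained weight vector
#'
#' A chemogenomic feature is a (chemical substructure, protein domain) pair
#' whose tensor pair feature carries a positive weight in the trained
#' classifier, interpreted as an association driving drug-target binding.
#' Features are ranked by decreasing weight; ties are broken
#' lexicographically by (substructure index, domain index).
#'
#' @param w a [`weight_vector`][train_classifier()].
#' @param space the [descriptor_space()] the model was trained over.
#' @param threshold keep features with weight strictly greater than this;
#'   default 0 ("positively weighted").
#'
#' @return A data frame of class `"chemogenomic_features"` with columns
#'   `rank`, `weight`, `substructure`, `domain`, `sub_index`, `dom_index`,
#'   ordered by rank.
#' @export
extract_features <- function(w, space, threshold = 0) {
  stopifnot(inherits(w, "weight_vector"), inherits(space, "descriptor_space"))
  sel <- which(w$weight > threshold)
  k <- w$index[sel]
  wt <- w$weight[sel]
  ij <- unpair_index(k, space)
  ord <- order(-wt, ij[, "i"], ij[, "j"])
  out <- data.frame(
    rank = seq_along(ord),
    weight = wt[ord],
    substructure = space$substructure_labels[ij[ord, "i"] + 1L],
    domain = space$domain_labels[ij[ord, "j"] + 1L],
    sub_index = as.integer(ij[ord, "i"]),
    dom_index = as.integer(ij[ord, "j"]),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("chemogenomic_features", "data.frame"))
}

#' Build a bipartite substructure-domain association network
#'
#' Keeps the features whose weight exceeds `weight_threshold` (the reference
#' visualization preset is 0.4) and assembles them into a weighted bipartite
#' graph with substructure and domain nodes.
#'
#' @param features a [`chemogenomic_features`][extract_features()] table.
#' @param weight_threshold keep edges with weight strictly greater than this.
#' @return An object of class `"association_network"`: list with the
#'   \pkg{igraph} `graph` (vertex attribute `type`: FALSE = substructure,
#'   TRUE = domain), the `edges` data frame and the named `degree` vector.
#' @seealso [largest_component()], [write_network()]
#' @export
build_network <- function(features, weight_threshold = 0.4) {
  stopifnot(inherits(features, "chemogenomic_features"))
  edges <- features[features$weight > weight_threshold, , drop = FALSE]
  subs <- unique(edges$substructure)
  doms <- unique(edges$domain)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$substructure, to = edges$domain,
               weight = edges$weight, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = c(subs, doms),
                          type = c(rep(FALSE, length(subs)),
                                   rep(TRUE, length(doms))),
                          stringsAsFactors = FALSE)
  )
  structure(
    list(graph = g, edges = edges, degree = igraph::degree(g),
         weight_threshold = weight_threshold),
    class = "association_network"
  )
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf(
    "association network: %d substructures + %d domains, %d edges (weight > %g)\n",
    sum(!igraph::V(x$graph)$type), sum(igraph::V(x$graph)$type),
    igraph::ecount(x$graph), x$weight_threshold
  ))
  invisible(x)
}

#' Maximal connected component of an association network
#'
#' @param network an [`association_network`][build_network()].
#' @return An `"association_network"` restricted to the largest connected
#'   component (ties broken by first component index).
#' @export
largest_component <- function(network) {
  stopifnot(inherits(network, "association_network"))
  comp <- igraph::components(network$graph)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(network$graph, keep)
  nodes <- igraph::V(g)$name
  edges <- network$edges[network$edges$substructure %in% nodes &
                           network$edges$domain %in% nodes, , drop = FALSE]
  structure(
    list(graph = g, edges = edges, degree = igraph::degree(g),
         weight_threshold = network$weight_threshold),
    class = "association_network"
  )
}

#' Overlap counts between named chemogenomic feature sets
#'
#' Computes, for every exclusive region of the set algebra over two or more
#' named feature sets (the regions a Venn diagram displays), the number of
#' unique (substructure, domain) pairs falling in exactly that combination
#' of sets.
#'
#' @param sets named list of feature sets; each element is either a
#'   [`chemogenomic_features`][extract_features()] table or a data frame with
#'   `substructure` and `domain` columns.
#' @return A data frame with one row per non-empty region: logical columns
#'   named after the sets and a `count` column. The attribute `"union_size"`
#'   holds the size of the union; region counts sum to it.
#' @export
compare_feature_sets <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)) || any(names(sets) == "")) {
    stop("need at least two named feature sets")
  }
  keys <- lapply(sets, function(s) {
    stopifnot(is.data.frame(s), all(c("substructure", "domain") %in% names(s)))
    unique(paste(s$substructure, s$domain, sep = "\r"))
  })
  all_keys <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  m <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1L, , drop = FALSE]
  names(patterns) <- names(sets)
  patterns$count <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(row) all(row == p)))
  })
  rownames(patterns) <- NULL
  structure(patterns, union_size = length(all_keys))
}

#' Write a ranked feature table to a tab-separated file
#'
#' Columns: `rank`, `weight`, `substructure`, `domain`. A `#`-prefixed header
#' records the model, `C` and convergence when `w` metadata is given.
#'
#' @param features a [`chemogenomic_features`][extract_features()] table.
#' @param path file path.
#' @param w optional [`weight_vector`][train_classifier()] whose metadata is
#'   written into the header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, w = NULL) {
  stopifnot(inherits(features, "chemogenomic_features"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(w)) {
    cat(sprintf("# model=%s C=%g converged=%s\n",
                w$model, w$C, isTRUE(w$converged)), file = con)
  }
  cat("rank\tweight\tsubstructure\tdomain\n", file = con)
  if (nrow(features) > 0L) {
    utils::write.table(
      features[, c("rank", "weight", "substructure", "domain")],
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path file path.
#' @param space a [descriptor_space()] used to recover descriptor indices.
#' @return A [`chemogenomic_features`][extract_features()] table.
#' @export
read_feature_table <- function(path, space) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  i <- match(df$substructure, space$substructure_labels) - 1L
  j <- match(df$domain, space$domain_labels) - 1L
  if (anyNA(i) || anyNA(j)) stop("feature table labels not in descriptor space")
  out <- data.frame(rank = df$rank, weight = df$weight,
                    substructure = df$substructure, domain = df$domain,
                    sub_index = i, dom_index = j, stringsAsFactors = FALSE)
  structure(out, class = c("chemogenomic_features", "data.frame"))
}

#' Export an association network
#'
#' @param network an [`association_network`][build_network()].
#' @param edge_tsv optional path for an edge-list TSV
#'   (`substructure<TAB>domain<TAB>weight`).
#' @param graphml optional path for a GraphML export.
#' @return The network, invisibly.
#' @export
write_network <- function(network, edge_tsv = NULL, graphml = NULL) {
  stopifnot(inherits(network, "association_network"))
  if (!is.null(edge_tsv)) {
    utils::write.table(
      network$edges[, c("substructure", "domain", "weight")],
      edge_tsv, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
  }
  invisible(network)
}
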