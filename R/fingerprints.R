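#' Build a fingerprint set from per-entity descriptor labels
#'
#' A fingerprint set holds one sparse binary fingerprint per compound or
#' protein: the sorted 0-based indices of the descriptors present in that
#' entity, relative to the set's own label vocabulary. The vocabulary is, by
#' default, the sorted union of the labels actually observed; descriptors
#' never seen in any entity are dropped (mirroring the usual practice of
#' discarding fingerprint bits that are constant zero in the data set). Pass
#' `declared_labels` to retain a full, fixed vocabulary instead.
#'
#' @param active_labels named list: entity id -> character vector of active
#'   descriptor labels (may be empty).
#' @param role `"compound"` or `"protein"`.
#' @param declared_labels optional character vector; when given, the
#'   vocabulary is exactly these labels (in the given order) and every
#'   observed label must be among them.
#'
#' @return An object of class `"fingerprint_set"` with fields `role`, `ids`,
#'   `labels` and `active` (named list of sorted 0-based integer vectors).
#'
#' @examples
#' fps <- fingerprint_set(list(d1 = c("SUB1"), d2 = c("SUB1", "SUB2")),
#'                        role = "compound")
#' fps$labels
#' fps$active
#'
#' @export
fingerprint_set <- function(active_labels, role = c("compound", "protein"),
                            declared_labels = NULL) {
  role <- match.arg(role)
  ids <- names(active_labels)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every fingerprint needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate ids in fingerprint set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  observed <- unique(unlist(active_labels, use.names = FALSE))
  if (is.null(declared_labels)) {
    labels <- sort(observed, method = "radix")
  } else {
    labels <- as.character(declared_labels)
    if (anyDuplicated(labels)) stop("duplicate labels in declared vocabulary")
    unknown <- setdiff(observed, labels)
    if (length(unknown) > 0L) {
      stop("labels absent from declared vocabulary: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  active <- lapply(active_labels, function(labs) {
    sort(match(unique(as.character(labs)), labels) - 1L)
  })
  names(active) <- ids
  structure(
    list(role = role, ids = ids, labels = labels, active = active),
    class = "fingerprint_set"
  )
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf(
    "fingerprint set: %d %ss over %d descriptors (mean %.1f active)\n",
    length(x$ids), x$role, length(x$labels),
    mean(lengths(x$active))
  ))
  invisible(x)
}

#' Extract one fingerprint from a set
#'
#' @param set a [fingerprint_set()].
#' @param id entity id.
#' @return An object of class `"compound_fingerprint"` or
#'   `"protein_fingerprint"`: a list with the entity id, the sorted 0-based
#'   `active` index set and the vocabulary size `n`.
#' @export
fingerprint <- function(set, id) {
  stopifnot(inherits(set, "fingerprint_set"))
  if (!id %in% set$ids) stop("unknown id: ", id)
  structure(
    list(id = id, active = set$active[[id]], n = length(set$labels)),
    class = paste0(set$role, "_fingerprint")
  )
}

#' Construct a single compound or protein fingerprint
#'
#' @param id entity id.
#' @param active sorted 0-based indices of the active descriptors.
#' @param n vocabulary size (`D` for compounds, `D_prime` for proteins).
#' @return A `"compound_fingerprint"` / `"protein_fingerprint"` object.
#' @export
compound_fingerprint <- function(id, active, n) {
  new_fingerprint(id, active, n, "compound_fingerprint")
}

#' @rdname compound_fingerprint
#' @export
protein_fingerprint <- function(id, active, n) {
  new_fingerprint(id, active, n, "protein_fingerprint")
}

new_fingerprint <- function(id, active, n, class) {
  active <- as.integer(active)
  n <- as.integer(n)
  if (length(active) > 0L) {
    if (is.unsorted(active, strictly = TRUE)) {
      stop("active indices must be strictly increasing")
    }
    if (active[1L] < 0L || active[length(active)] >= n) {
      stop(sprintf("active indices out of range [0, %d)", n))
    }
  }
  structure(list(id = id, active = active, n = n), class = class)
}

#' Read fingerprints from a tab-separated file
#'
#' Expected format: one row per entity, `id<TAB>label1,label2,...`. The label
#' field may be empty (an all-zero fingerprint). Lines starting with `#` and
#' blank lines are ignored. The file must be UTF-8.
#'
#' @param path file path.
#' @inheritParams fingerprint_set
#' @return A [fingerprint_set()].
#' @seealso [write_fingerprints()]
#' @export
read_fingerprints <- function(path, role = c("compound", "protein"),
                              declared_labels = NULL) {
  role <- match.arg(role)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  active <- vector("list", length(lines))
  ids <- character(length(lines))
  for (r in seq_along(lines)) {
    f <- strsplit(lines[r], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 1L || length(f) > 2L || f[1L] == "") {
      stop(sprintf("%s line %d: malformed fingerprint row", path, lineno[r]))
    }
    ids[r] <- f[1L]
    labs <- if (length(f) == 2L && nzchar(f[2L])) {
      strsplit(f[2L], ",", fixed = TRUE)[[1L]]
    } else {
      character(0)
    }
    if (any(labs == "")) {
      stop(sprintf("%s line %d: empty descriptor label", path, lineno[r]))
    }
    active[[r]] <- labs
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    stop(sprintf("%s line %d: duplicate id '%s'",
                 path, lineno[which(dup)[1L]], ids[which(dup)[1L]]))
  }
  names(active) <- ids
  fingerprint_set(active, role = role, declared_labels = declared_labels)
}

#' Write fingerprints to a tab-separated file
#'
#' Inverse of [read_fingerprints()]: rows are `id<TAB>label1,label2,...`.
#'
#' @param set a [fingerprint_set()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(set, path) {
  stopifnot(inherits(set, "fingerprint_set"))
  rows <- vapply(set$ids, function(id) {
    paste0(id, "\t", paste(set$labels[set$active[[id]] + 1L], collapse = ","))
  }, character(1))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Build the descriptor space spanned by a compound and a protein set
#'
#' @param compounds a compound [fingerprint_set()].
#' @param proteins a protein [fingerprint_set()].
#' @return A [descriptor_space()] whose substructure labels are the compound
#'   set's vocabulary and whose domain labels are the protein set's.
#' @export
combined_space <- function(compounds, proteins) {
  stopifnot(inherits(compounds, "fingerprint_set"),
            inherits(proteins, "fingerprint_set"))
  if (compounds$role != "compound" || proteins$role != "protein") {
    stop("combined_space() expects a compound set and a protein set")
  }
  descriptor_space(compounds$labels, proteins$labels)
}
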