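#' Labeled drug-target interaction data
#'
#' An interaction dataset is a data frame of (compound id, protein id, label)
#' triples with labels in {+1, -1}: known interacting pairs (the gold
#' standard positives) and, after negative sampling, presumed non-interacting
#' pairs. Duplicate (compound, protein) entries are rejected rather than
#' silently deduplicated.
#'
#' @param compound_id character vector of compound ids.
#' @param protein_id character vector of protein ids.
#' @param label numeric vector of +1/-1 labels; defaults to all +1.
#'
#' @return A data frame of class `"interaction_dataset"` with columns
#'   `compound_id`, `protein_id`, `label`.
#' @export
interaction_dataset <- function(compound_id, protein_id,
                                label = rep(1, length(compound_id))) {
  compound_id <- as.character(compound_id)
  protein_id <- as.character(protein_id)
  label <- as.numeric(label)
  if (length(protein_id) != length(compound_id) ||
      length(label) != length(compound_id)) {
    stop("compound_id, protein_id and label must have equal lengths")
  }
  if (!all(label %in% c(-1, 1))) stop("labels must be +1 or -1")
  key <- paste(compound_id, protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (compound, protein) pair: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  structure(
    data.frame(compound_id = compound_id, protein_id = protein_id,
               label = label, stringsAsFactors = FALSE),
    class = c("interaction_dataset", "data.frame")
  )
}

#' Read an interaction list from a tab-separated file
#'
#' Rows are `compound_id<TAB>protein_id[<TAB>label]` with label `+1`/`1` or
#' `-1`; a missing label column means +1 (a gold-standard positive). Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @param compounds,proteins optional [fingerprint_set()]s; when given, every
#'   id in the file must resolve to a fingerprint.
#' @return An [interaction_dataset()].
#' @export
read_interactions <- function(path, compounds = NULL, proteins = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  cid <- pid <- character(length(lines))
  lab <- numeric(length(lines))
  for (r in seq_along(lines)) {
    f <- strsplit(lines[r], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || length(f) > 3L || f[1L] == "" || f[2L] == "") {
      stop(sprintf("%s line %d: malformed interaction row", path, lineno[r]))
    }
    cid[r] <- f[1L]
    pid[r] <- f[2L]
    lab[r] <- if (length(f) == 3L) {
      if (!f[3L] %in% c("1", "+1", "-1")) {
        stop(sprintf("%s line %d: label must be +1 or -1, got '%s'",
                     path, lineno[r], f[3L]))
      }
      as.numeric(f[3L])
    } else {
      1
    }
    if (!is.null(compounds) && !cid[r] %in% compounds$ids) {
      stop(sprintf("%s line %d: unknown compound id '%s'",
                   path, lineno[r], cid[r]))
    }
    if (!is.null(proteins) && !pid[r] %in% proteins$ids) {
      stop(sprintf("%s line %d: unknown protein id '%s'",
                   path, lineno[r], pid[r]))
    }
  }
  key <- paste(cid, pid, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("%s line %d: duplicate pair (%s, %s)",
                 path, lineno[dup[1L]], cid[dup[1L]], pid[dup[1L]]))
  }
  interaction_dataset(cid, pid, lab)
}

#' Write an interaction dataset to a tab-separated file
#'
#' @param data an [interaction_dataset()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(data, path) {
  stopifnot(inherits(data, "interaction_dataset"))
  rows <- sprintf("%s\t%s\t%+d", data$compound_id, data$protein_id,
                  as.integer(data$label))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
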