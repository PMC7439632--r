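# Featurization: convert path collections into binary feature matrices.
# Two representations of indirect paths are supported:
#   metapath - the ordered predicate sequence of an indirect path is one
#              feature ("indirect|p1->p2");
#   split    - each predicate of an indirect path is its own feature.
# Three direction modes control whether predicates carry their traversal
# orientation (:fwd / :rev, relative to the first-disease side):
#   undirected - no predicate carries orientation;
#   mixed      - only predicates categorized as directed by the
#                directionality table carry orientation;
#   directed   - every predicate carries orientation, including self-loop
#                predicates (marked :loop).
# In undirected and mixed modes self-loop predicates of the overlap scenario
# are always orientation-free (subject and object are the same protein).
# All features are binary (presence of at least one path with the signature).

#' Define a feature-set variant
#'
#' @param representation `"metapath"` or `"split"` — how indirect paths are
#'   encoded.
#' @param direction_mode `"undirected"`, `"mixed"`, or `"directed"`.
#' @return an object of class `feature_variant`.
#' @export
feature_variant <- function(representation = c("metapath", "split"),
                            direction_mode = c("undirected", "mixed", "directed")) {
  structure(list(representation = match.arg(representation),
                 direction_mode = match.arg(direction_mode)),
            class = "feature_variant")
}

#' @export
print.feature_variant <- function(x, ...) {
  cat(sprintf("<feature_variant> %s / %s\n", x$representation, x$direction_mode))
  invisible(x)
}

#' @export
format.feature_variant <- function(x, ...) {
  paste(x$representation, x$direction_mode, sep = "_")
}

#' The four primary feature-set variants
#'
#' `{metapath, split} x {undirected, mixed}`; set `include_directed = TRUE`
#' to append the two all-directed variants.
#'
#' @param include_directed also return the all-directed variation.
#' @return named list of [feature_variant()] objects.
#' @export
primary_variants <- function(include_directed = FALSE) {
  reps <- c("metapath", "split")
  modes <- c("undirected", "mixed")
  if (include_directed) modes <- c(modes, "directed")
  out <- list()
  for (r in reps) for (m in modes) {
    v <- feature_variant(r, m)
    out[[format(v)]] <- v
  }
  out
}

# component string for one edge: predicate, orientation in {fwd, rev, loop},
# oriented flag (logical) per the direction mode
.component <- function(predicate, orientation, oriented) {
  ifelse(oriented, paste0(predicate, ":", orientation), predicate)
}

# logical: does this edge keep its orientation under the mode?
.oriented <- function(predicate, orientation, mode, table) {
  if (mode == "undirected") return(rep(FALSE, length(predicate)))
  if (mode == "directed") return(rep(TRUE, length(predicate)))
  # mixed: directed predicates only, and never on loop edges
  is_dir <- categorize_predicate(predicate, table) == "directed"
  is_dir & orientation != "loop"
}

#' Feature signatures of a single path instance
#'
#' @param path a path instance as produced by [as_path_list()].
#' @param variant a [feature_variant()].
#' @param table a [directionality_table()]; required for `mixed` mode.
#' @return character vector of signature strings
#'   (`scenario|component[->component]`).  A loop-free overlap path yields
#'   the bare signature `"overlap"`; loop predicates add one signature each.
#' @export
path_signatures <- function(path, variant, table = NULL) {
  stopifnot(inherits(variant, "feature_variant"))
  mode <- variant$direction_mode
  if (mode == "mixed" && is.null(table)) {
    stop("mixed direction mode requires a directionality table", call. = FALSE)
  }
  ed <- path$edges
  if (path$scenario == "overlap") {
    sigs <- "overlap"
    if (nrow(ed) > 0) {
      oriented <- .oriented(ed$predicate, ed$orientation, mode, table)
      sigs <- c(sigs, paste0("overlap|",
                             .component(ed$predicate, ed$orientation, oriented)))
    }
    return(sort(unique(sigs)))
  }
  oriented <- .oriented(ed$predicate, ed$orientation, mode, table)
  comp <- .component(ed$predicate, ed$orientation, oriented)
  if (path$scenario == "direct") {
    return(paste0("direct|", comp))
  }
  # indirect
  if (variant$representation == "metapath") {
    paste0("indirect|", paste(comp, collapse = "->"))
  } else {
    sort(unique(paste0("indirect|", comp)))
  }
}

# Vectorized signature computation for a whole path_collection.
# Returns a character vector of (non-unique) signatures.
.collection_signatures <- function(paths, variant, table) {
  mode <- variant$direction_mode
  sigs <- character()
  if (nrow(paths$overlap) > 0) sigs <- c(sigs, "overlap")
  ol <- paths$overlap_loops
  if (nrow(ol) > 0) {
    oriented <- .oriented(ol$predicate, rep("loop", nrow(ol)), mode, table)
    sigs <- c(sigs, paste0("overlap|",
                           .component(ol$predicate, "loop", oriented)))
  }
  d <- paths$direct
  if (nrow(d) > 0) {
    oriented <- .oriented(d$predicate, d$orient, mode, table)
    sigs <- c(sigs, paste0("direct|", .component(d$predicate, d$orient, oriented)))
  }
  ind <- paths$indirect
  if (nrow(ind) > 0) {
    or1 <- .oriented(ind$p1, ind$o1, mode, table)
    or2 <- .oriented(ind$p2, ind$o2, mode, table)
    c1 <- .component(ind$p1, ind$o1, or1)
    c2 <- .component(ind$p2, ind$o2, or2)
    if (variant$representation == "metapath") {
      sigs <- c(sigs, paste0("indirect|", c1, "->", c2))
    } else {
      sigs <- c(sigs, paste0("indirect|", c1), paste0("indirect|", c2))
    }
  }
  unique(sigs)
}

#' Extract paths for every candidate pair
#'
#' Runs [extract_paths()] once per candidate so that several feature variants
#' can be built from the same path collections.
#'
#' @param candidates a [candidate_pairs()] set.
#' @param kg a [knowledge_graph()].
#' @param ... passed to [extract_paths()].
#' @return named list of `path_collection` objects, one per `pair_id`.
#' @export
extract_candidate_paths <- function(candidates, kg, ...) {
  stopifnot(inherits(candidates, "candidate_set"))
  out <- vector("list", nrow(candidates))
  names(out) <- candidates$pair_id
  for (i in seq_len(nrow(candidates))) {
    out[[i]] <- extract_paths(kg, candidates$proteins_first[[i]],
                              candidates$proteins_second[[i]], ...)
  }
  out
}

#' Build the binary feature matrix from per-candidate path collections
#'
#' @param path_list named list of `path_collection`s (see
#'   [extract_candidate_paths()]); names are candidate pair ids.
#' @param variant a [feature_variant()].
#' @param table a [directionality_table()] (needed for `mixed` mode).
#' @param labels optional factor/character labels aligned with `path_list`.
#' @return an object of class `feature_matrix`: a list with the sparse
#'   logical `matrix` (rows = candidates, columns = lexicographically sorted
#'   signatures), the `variant`, and `labels`.  Candidates without any path
#'   produce an all-false row.
#' @export
featurize_paths <- function(path_list, variant, table = NULL, labels = NULL) {
  if (length(path_list) == 0) stop("empty candidate list", call. = FALSE)
  stopifnot(inherits(variant, "feature_variant"))
  per <- lapply(path_list, .collection_signatures, variant = variant, table = table)
  cols <- sort(unique(unlist(per, use.names = FALSE)))
  ii <- rep.int(seq_along(per), lengths(per))
  jj <- match(unlist(per, use.names = FALSE), cols)
  mat <- Matrix::sparseMatrix(
    i = ii, j = jj, x = TRUE,
    dims = c(length(per), length(cols)),
    dimnames = list(names(path_list), cols)
  )
  structure(list(matrix = mat, variant = variant, labels = labels),
            class = "feature_matrix")
}

#' Extract paths and featurize in one step
#'
#' Convenience wrapper: [extract_candidate_paths()] + [featurize_paths()].
#'
#' @inheritParams extract_candidate_paths
#' @inheritParams featurize_paths
#' @return a `feature_matrix`; labels are taken from the candidate set.
#' @export
build_feature_matrix <- function(candidates, kg, variant, table = NULL, ...) {
  paths <- extract_candidate_paths(candidates, kg, ...)
  featurize_paths(paths, variant, table, labels = candidates$label)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d candidates x %d binary features (%.2f%% filled)\n",
              format(x$variant), nrow(x$matrix), ncol(x$matrix),
              100 * Matrix::nnzero(x$matrix) / max(1, prod(dim(x$matrix)))))
  invisible(x)
}

#' Write a feature matrix as plain-text sparse triplet files
#'
#' Emits `<prefix>_rows.tsv` (pair ids), `<prefix>_cols.tsv` (the signature
#' glossary), and `<prefix>_cells.tsv` (1-based row/col coordinates of TRUE
#' cells).
#'
#' @param fm a `feature_matrix`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- as(fm$matrix, "TsparseMatrix")
  paths <- paste0(prefix, c("_rows.tsv", "_cols.tsv", "_cells.tsv"))
  writeLines(rownames(fm$matrix), paths[1])
  writeLines(colnames(fm$matrix), paths[2])
  fwrite(data.table(row = m@i + 1L, col = m@j + 1L)[order(row, col)],
         paths[3], sep = "\t")
  invisible(paths)
}
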